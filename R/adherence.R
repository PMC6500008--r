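#' Surveillance adherence classification
#'
#' Guideline minima for stage II/III colon cancer surveillance are two CEA
#' tests per year, one CT (or PET) scan per year, and a colonoscopy about
#' one year after resection. Each complete follow-up year is labelled
#' More Adherent, Less Adherent or Nonadherent from the year's deduplicated
#' test counts; yearly labels are then combined into an overall label.
#'
#' The yearly rule counts *active modalities*: CEA is active with at least
#' one test, CT with at least one scan, and colonoscopy with at least one
#' scope in the current year or (from year 2 on) in the previous year — a
#' scope performed around the 1-year mark covers the adjacent assessment
#' year. A year with no tests at all and no colonoscopy carry-over is
#' Nonadherent; exactly one active modality is Less Adherent; two or more
#' are More Adherent. A year with zero current-year tests but a carried
#' colonoscopy is Less Adherent, never Nonadherent.
#'
#' @name adherence
NULL

LBL_MORE <- "MORE"
LBL_LESS <- "LESS"
LBL_NON <- "NONADHERENT"
LBL_EXCL <- "EXCLUDED"

#' Construct a yearly-classification rule table
#'
#' The default rule is the active-modality scheme described in
#' [adherence]. `overrides` allows individual count-category tuples to be
#' re-mapped without code change, so an exact published enumeration can be
#' dropped in: a data frame with columns `year` (1-3, or NA for any year),
#' `cea_cat` (`"0"`, `"1"`, `"2+"`), `ct_cat` (`"0"`, `"1+"`), `scope_cat`
#' (`"0"`, `"1+"`), `carry` (logical, colonoscopy carry-over active) and
#' `label`.
#'
#' @param cea_min,ct_min,scope_min Guideline minima per year.
#' @param carry_over Whether a prior-year colonoscopy counts in years 2-3.
#' @param overrides Optional tuple-level label overrides (see above).
#' @return An object of class `rule_table`.
#' @export
rule_table <- function(cea_min = 2L, ct_min = 1L, scope_min = 1L,
                       carry_over = TRUE, overrides = NULL) {
  if (!is.null(overrides)) {
    need <- c("year", "cea_cat", "ct_cat", "scope_cat", "carry", "label")
    stopifnot(is.data.frame(overrides), all(need %in% names(overrides)),
              all(overrides$label %in% c(LBL_MORE, LBL_LESS, LBL_NON)))
  }
  structure(list(cea_min = cea_min, ct_min = ct_min, scope_min = scope_min,
                 carry_over = carry_over, overrides = overrides),
            class = "rule_table")
}

count_cats <- function(cea, ct, scope) {
  list(cea = if (cea >= 2) "2+" else as.character(cea),
       ct = if (ct >= 1) "1+" else "0",
       scope = if (scope >= 1) "1+" else "0")
}

#' Classify one follow-up year
#'
#' @param year_index Assessment year, 1-3.
#' @param cea_count,ct_count,scope_count Deduplicated test counts for the
#'   year.
#' @param prior_year_scope_count Colonoscopy count in the previous year
#'   (0 for year 1).
#' @param rules A [rule_table()].
#' @return `"MORE"`, `"LESS"` or `"NONADHERENT"`.
#' @examples
#' classify_year(1, 2, 1, 1)  # MORE
#' classify_year(1, 3, 0, 0)  # LESS
#' classify_year(2, 0, 0, 0, prior_year_scope_count = 1)  # LESS (carry-over)
#' @export
classify_year <- function(year_index, cea_count, ct_count, scope_count,
                          prior_year_scope_count = 0L, rules = rule_table()) {
  counts <- c(cea_count, ct_count, scope_count, prior_year_scope_count)
  if (any(counts < 0)) stop("test counts must be nonnegative")
  stopifnot(year_index %in% 1:3)
  if (year_index == 1L) prior_year_scope_count <- 0L

  carry <- rules$carry_over && year_index >= 2L && prior_year_scope_count >= 1L

  if (!is.null(rules$overrides)) {
    cc <- count_cats(cea_count, ct_count, scope_count)
    ov <- rules$overrides
    hit <- (is.na(ov$year) | ov$year == year_index) &
      ov$cea_cat == cc$cea & ov$ct_cat == cc$ct &
      ov$scope_cat == cc$scope & ov$carry == carry
    if (any(hit)) return(ov$label[which(hit)[1L]])
  }

  active <- (cea_count >= 1) + (ct_count >= 1) + (scope_count >= 1 || carry)
  if (cea_count == 0 && ct_count == 0 && scope_count == 0 && !carry)
    return(LBL_NON)
  if (active >= 2) LBL_MORE else LBL_LESS
}

#' Combine yearly labels into an overall surveillance classification
#'
#' Patients with no complete follow-up year, or whose every complete year
#' is Nonadherent (no surveillance tests at all during the assessment
#' period), are excluded from the analysis. With one complete year the
#' overall label is that year's label. With two or three, Nonadherent
#' years count as Less Adherent, and the patient is More Adherent iff
#' strictly more years were More than Less; ties go to Less Adherent.
#'
#' @param yearly Character vector of 0-3 yearly labels for consecutive
#'   complete years starting at year 1.
#' @param more_if Alternative combination rule, a function taking the
#'   counts `(n_more, n_less)` and returning TRUE for More Adherent; the
#'   default is the strict-majority rule.
#' @return `"MORE"`, `"LESS"` or `"EXCLUDED"`.
#' @examples
#' classify_overall(c("MORE"))                    # MORE
#' classify_overall(c("MORE", "LESS"))            # LESS (tie)
#' classify_overall(c("MORE", "MORE", "LESS"))    # MORE
#' classify_overall(rep("NONADHERENT", 3))        # EXCLUDED
#' @export
classify_overall <- function(yearly, more_if = NULL) {
  stopifnot(all(yearly %in% c(LBL_MORE, LBL_LESS, LBL_NON)), length(yearly) <= 3)
  if (length(yearly) == 0L) return(LBL_EXCL)
  if (all(yearly == LBL_NON)) return(LBL_EXCL)
  if (length(yearly) == 1L) return(yearly)
  n_more <- sum(yearly == LBL_MORE)
  n_less <- sum(yearly %in% c(LBL_LESS, LBL_NON))
  more <- if (is.null(more_if)) n_more > n_less else more_if(n_more, n_less)
  if (more) LBL_MORE else LBL_LESS
}

#' Build per-patient surveillance profiles
#'
#' Applies [classify_year()] to each complete follow-up year and
#' [classify_overall()] to the resulting labels, for every patient in the
#' counts table.
#'
#' @param counts Data frame from [summarize_claims()]: `patient_id`,
#'   `cea_1..3`, `ct_1..3`, `scope_1..3`.
#' @param treatment Data frame with `patient_id` and `complete_years`.
#' @param rules A [rule_table()].
#' @return Data frame with one row per patient: the counts, `complete_years`,
#'   `year1`-`year3` labels (NA for incomplete years), `overall`, and
#'   `exclusion_reason` (`""`, `"no_complete_year"` or `"nonadherent"`).
#' @export
build_profiles <- function(counts, treatment, rules = rule_table()) {
  miss <- setdiff(counts$patient_id, treatment$patient_id)
  if (length(miss))
    stop("patients missing completeness info: ", paste(head(miss), collapse = ", "))
  ord <- match(counts$patient_id, treatment$patient_id)
  ny <- treatment$complete_years[ord]

  n <- nrow(counts)
  yl <- matrix(NA_character_, n, 3, dimnames = list(NULL, paste0("year", 1:3)))
  overall <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    labs <- character(0)
    for (k in seq_len(ny[i])) {
      labs[k] <- classify_year(
        k,
        counts[[paste0("cea_", k)]][i],
        counts[[paste0("ct_", k)]][i],
        counts[[paste0("scope_", k)]][i],
        prior_year_scope_count = if (k >= 2) counts[[paste0("scope_", k - 1)]][i] else 0L,
        rules = rules)
      yl[i, k] <- labs[k]
    }
    overall[i] <- classify_overall(labs)
    reason[i] <- if (overall[i] != LBL_EXCL) "" else
      if (ny[i] == 0L) "no_complete_year" else "nonadherent"
  }
  out <- cbind(counts,
               data.frame(complete_years = ny, yl, overall = overall,
                          exclusion_reason = reason))
  rownames(out) <- NULL
  out
}

#' Frequencies of overall surveillance labels
#'
#' @param profiles Output of [build_profiles()].
#' @return Named integer vector over MORE, LESS, EXCLUDED.
#' @export
label_frequencies <- function(profiles) {
  table(factor(profiles$overall, levels = c(LBL_MORE, LBL_LESS, LBL_EXCL)))
}
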