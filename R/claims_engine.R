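#' Claims processing: treatment anchor and surveillance test counting
#'
#' These functions turn raw dated service claims into the quantities the
#' surveillance-adherence analysis is built on: a per-patient *final
#' treatment date* that anchors follow-up, deduplicated surveillance test
#' days, and per-year test counts for the first three post-treatment years.
#'
#' All dates are integer day offsets from a nominal diagnosis epoch; only
#' day arithmetic matters. "Six months" is rendered as 183 days and a
#' follow-up "year" as 365 days, half-open `[start, start + 365)`.
#'
#' @name claims_engine
NULL

# closed set of claim event types; CT and PET are pooled downstream
CLAIM_TYPES <- c("surgery", "chemo", "CEA", "CT", "PET", "colonoscopy")

#' Final treatment date from surgery and chemotherapy claims
#'
#' Patients treated with surgery alone are anchored at the surgery date.
#' For patients who received adjuvant chemotherapy, claims no more than 90
#' days apart are treated as one sequential course starting at the first
#' chemotherapy claim; the anchor is the last day of that course, capped at
#' 183 days (6 months) after the first chemotherapy claim for courses that
#' run longer. Chemotherapy claims after a gap of more than 90 days do not
#' re-anchor the date.
#'
#' @param surgery_day Integer day of resection.
#' @param chemo_days Sorted ascending integer days of chemotherapy claims
#'   (may be empty).
#' @return A list with `surgery_day`, `final_treatment_day`, and `modality`
#'   (`"surgery_only"` or `"surgery_plus_chemo"`).
#' @examples
#' final_treatment_date(0, integer(0))$final_treatment_day  # 0
#' final_treatment_date(0, c(30, 60, 90, 150))$final_treatment_day  # 150
#' final_treatment_date(0, c(30, 90, 150, 210, 270))$final_treatment_day  # 213
#' @export
final_treatment_date <- function(surgery_day, chemo_days = integer(0)) {
  stopifnot(length(surgery_day) == 1L, is.finite(surgery_day))
  chemo_days <- as.numeric(chemo_days)
  if (length(chemo_days) == 0L) {
    return(list(surgery_day = surgery_day,
                final_treatment_day = surgery_day,
                modality = "surgery_only"))
  }
  if (is.unsorted(chemo_days, strictly = FALSE))
    stop("chemo_days must be sorted ascending")
  if (chemo_days[1L] < surgery_day)
    stop("chemotherapy claim precedes surgery")
  first <- chemo_days[1L]
  run_end <- first
  for (d in chemo_days[-1L]) {
    if (d - run_end <= 90) run_end <- d else break
  }
  final <- if (run_end - first > 183) first + 183 else run_end
  list(surgery_day = surgery_day,
       final_treatment_day = final,
       modality = "surgery_plus_chemo")
}

#' Deduplicate surveillance test claims with a minimum-gap rule
#'
#' Claims for the same test separated by fewer than `min_gap` days are
#' treated as duplicate billing for one test. The scan is greedy from the
#' earliest claim: the first claim is kept, and each later claim is kept
#' iff it falls at least `min_gap` days after the last kept claim. CT and
#' PET claims should be pooled into one stream before calling this.
#'
#' @param days Sorted ascending numeric days of one patient's claims for
#'   one test modality.
#' @param min_gap Minimum separation in days (default 30).
#' @return The retained claim days (subset of `days`).
#' @examples
#' dedupe_tests(c(100, 100, 115))   # 100
#' dedupe_tests(c(100, 130, 159))   # 100 130
#' @export
dedupe_tests <- function(days, min_gap = 30) {
  days <- as.numeric(days)
  if (length(days) == 0L) return(numeric(0))
  if (is.unsorted(days, strictly = FALSE))
    stop("days must be sorted ascending")
  kept <- days[1L]
  last <- days[1L]
  for (d in days[-1L]) {
    if (d - last >= min_gap) {
      kept <- c(kept, d)
      last <- d
    }
  }
  kept
}

#' Count retained test days per post-treatment year
#'
#' Year k (k = 1, 2, 3) covers days
#' `[final + 365 * (k - 1), final + 365 * k)`. Events before the final
#' treatment date or after year 3 are ignored.
#'
#' @param days Retained (deduplicated) test days.
#' @param final_treatment_day The follow-up anchor.
#' @return Integer vector of length 3, counts for years 1-3.
#' @export
count_by_year <- function(days, final_treatment_day) {
  off <- as.numeric(days) - final_treatment_day
  yr <- floor(off / 365) + 1
  counts <- integer(3)
  for (k in 1:3) counts[k] <- sum(off >= 0 & yr == k)
  counts
}

#' Number of complete post-treatment follow-up years
#'
#' Year k is complete iff the patient was followed (alive and uncensored)
#' through day `final + 365 * k`. Capped at 3; patients with 0 complete
#' years are excluded from the adherence analysis downstream.
#'
#' @param final_treatment_day Follow-up anchor.
#' @param last_followup_day `min(death day, censor day)`.
#' @return Integer in 0:3.
#' @export
complete_years <- function(final_treatment_day, last_followup_day) {
  if (last_followup_day < final_treatment_day)
    stop("follow-up ends before the final treatment date")
  min(3L, as.integer(floor((last_followup_day - final_treatment_day) / 365)))
}

#' Per-patient treatment summaries and surveillance counts from claims
#'
#' Runs the full claims engine over a cohort: anchors each patient at the
#' final treatment date, pools CT with PET, deduplicates each surveillance
#' modality stream (CEA, CT/PET, colonoscopy) over the whole post-treatment
#' period with the 30-day rule, and windows the retained days into
#' follow-up years 1-3.
#'
#' @param patients Data frame with columns `patient_id` and
#'   `last_followup_day` (death or censor day).
#' @param claims Data frame with columns `patient_id`, `event_type` (one of
#'   `r paste(CLAIM_TYPES, collapse = ", ")`), `service_day`.
#' @param min_gap Deduplication gap in days.
#' @return A list of two data frames: `treatment` (patient_id, surgery_day,
#'   final_treatment_day, modality, complete_years) and `counts`
#'   (patient_id, cea_1..3, ct_1..3, scope_1..3).
#' @export
summarize_claims <- function(patients, claims, min_gap = 30) {
  stopifnot(all(c("patient_id", "last_followup_day") %in% names(patients)),
            all(c("patient_id", "event_type", "service_day") %in% names(claims)))
  bad <- setdiff(unique(claims$event_type), CLAIM_TYPES)
  if (length(bad))
    stop("unknown event types: ", paste(bad, collapse = ", "))

  ids <- patients$patient_id
  cl_split <- split(claims[c("event_type", "service_day")],
                    factor(claims$patient_id, levels = ids))

  n <- length(ids)
  treat <- data.frame(patient_id = ids, surgery_day = NA_real_,
                      final_treatment_day = NA_real_,
                      modality = NA_character_, complete_years = NA_integer_)
  cnt <- matrix(0L, n, 9,
                dimnames = list(NULL, c(paste0("cea_", 1:3),
                                        paste0("ct_", 1:3),
                                        paste0("scope_", 1:3))))
  for (i in seq_len(n)) {
    ev <- cl_split[[i]]
    surg <- ev$service_day[ev$event_type == "surgery"]
    if (length(surg) != 1L)
      stop("patient ", ids[i], ": expected exactly one surgery claim, got ",
           length(surg))
    chemo <- sort(ev$service_day[ev$event_type == "chemo"])
    ts <- final_treatment_date(surg, chemo)
    treat$surgery_day[i] <- ts$surgery_day
    treat$final_treatment_day[i] <- ts$final_treatment_day
    treat$modality[i] <- ts$modality
    treat$complete_years[i] <-
      complete_years(ts$final_treatment_day, patients$last_followup_day[i])

    streams <- list(
      cea = ev$service_day[ev$event_type == "CEA"],
      ct = ev$service_day[ev$event_type %in% c("CT", "PET")],
      scope = ev$service_day[ev$event_type == "colonoscopy"])
    for (m in names(streams)) {
      d <- sort(streams[[m]])
      d <- d[d >= ts$final_treatment_day]  # dedup runs on the post-treatment stream
      kept <- dedupe_tests(d, min_gap = min_gap)
      cnt[i, paste0(m, "_", 1:3)] <- count_by_year(kept, ts$final_treatment_day)
    }
  }
  list(treatment = treat, counts = cbind(data.frame(patient_id = ids),
                                         as.data.frame(cnt)))
}
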