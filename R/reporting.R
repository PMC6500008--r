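#' Descriptive and summary reporting
#'
#' Builds the descriptive characteristics table (counts and column
#' percentages by surveillance group, Pearson chi-square per
#' characteristic, follow-up medians and 25% cancer-death times), the
#' hazard-ratio summary table, and the one-command pipeline runner.
#'
#' @name reporting
NULL

#' Column percentages to one decimal
#'
#' @param counts Integer vector of category counts for one group.
#' @return Percentages of the column total, rounded to one decimal.
#' @export
column_percent <- function(counts) round(100 * counts / sum(counts), 1)

fmt_p <- function(p) ifelse(p < 1e-3, "< 0.001", sprintf("%.3f", p))

#' Descriptive comparison of the surveillance groups
#'
#' One block per characteristic with per-group counts and column
#' percentages and a Pearson chi-square test on the count
#' cross-tabulation; vital status at 5 years and cause of death among the
#' deceased are reported the same way (cause-of-death percentages use the
#' deceased count as denominator). Median follow-up (reverse
#' Kaplan-Meier) and the 25% cancer-death time are computed per group with
#' log-rank comparisons.
#'
#' @param patients,treatment,profiles Cohort tables; only patients with an
#'   overall label of MORE or LESS enter.
#' @param characteristics Categorical patient columns to tabulate.
#' @return List: `groups` (n and share per group), `rows` (long data
#'   frame: characteristic, category, per-group count and pct), `tests`
#'   (chi-square per characteristic), `followup` (medians and 25%
#'   cancer-death times in years, with log-rank p).
#' @export
descriptive_table <- function(patients, treatment, profiles,
                              characteristics = intersect(
                                c("age_group", "race", "sex", "marital",
                                  "dx_year", "buyin", "poverty", "urban",
                                  "region", "stage", "grade", "site"),
                                names(patients))) {
  keep <- profiles$overall %in% c(LBL_MORE, LBL_LESS)
  ids <- profiles$patient_id[keep]
  grp <- factor(profiles$overall[keep], levels = c(LBL_MORE, LBL_LESS))
  if (any(table(grp) == 0)) stop("empty surveillance group")
  pat <- patients[match(ids, patients$patient_id), ]
  fin <- treatment$final_treatment_day[match(ids, treatment$patient_id)]

  groups <- data.frame(group = levels(grp),
                       n = as.integer(table(grp)),
                       pct = column_percent(as.integer(table(grp))))

  # vital status at the 5-year horizon and cause of death among deceased
  t_days <- pat$last_followup_day - fin
  dead5 <- !is.na(pat$death_day) & t_days <= 5 * 365
  vital <- table(ifelse(dead5, "deceased", "alive"), grp)
  cod <- table(pat$cause[dead5], grp[dead5])

  rows <- list()
  tests <- list()
  add_block <- function(name, tab) {
    cnt <- as.matrix(tab)
    pct <- apply(cnt, 2, column_percent)
    rows[[name]] <<- data.frame(
      characteristic = name, category = rownames(cnt),
      n_more = cnt[, 1], pct_more = pct[, 1],
      n_less = cnt[, 2], pct_less = pct[, 2], row.names = NULL)
    cs <- suppressWarnings(stats::chisq.test(cnt, correct = FALSE))
    tests[[name]] <<- data.frame(
      characteristic = name, statistic = unname(cs$statistic),
      df = unname(cs$parameter), p_value = unname(cs$p.value),
      p_printed = fmt_p(unname(cs$p.value)), row.names = NULL)
  }
  add_block("vital_status_5yr", vital)
  add_block("cause_of_death", cod)
  for (v in characteristics) add_block(v, table(pat[[v]], grp))
  if ("chemo" %in% names(pat))
    add_block("chemotherapy", table(ifelse(pat$chemo == 1, "yes", "no"), grp))

  # follow-up medians (reverse KM) and 25% cancer-death times, in years
  fu <- lapply(levels(grp), function(g) {
    sel <- grp == g
    died <- as.integer(!is.na(pat$death_day[sel]))
    med <- median_followup(t_days[sel], died) / 365
    canc <- as.integer(!is.na(pat$death_day[sel]) & pat$cause[sel] == "cancer")
    q25 <- km_quantile(weighted_km(t_days[sel], canc), 0.25) / 365
    data.frame(group = g, median_followup_years = med,
               cancer_death_25pct_years = q25)
  })
  died_all <- as.integer(!is.na(pat$death_day))
  canc_all <- as.integer(!is.na(pat$death_day) & pat$cause == "cancer")
  lr_fu <- weighted_logrank(t_days, 1L - died_all, grp)
  lr_cd <- weighted_logrank(t_days, canc_all, grp)
  followup <- do.call(rbind, fu)
  followup$p_followup <- fmt_p(lr_fu$p_value)
  followup$p_cancer_death <- fmt_p(lr_cd$p_value)

  list(groups = groups, rows = do.call(rbind, rows),
       tests = do.call(rbind, tests), followup = followup)
}

#' Hazard-ratio summary table
#'
#' @param fits Named list of `survfit_iptw` fits (or NULL entries for
#'   unavailable outcomes), e.g. from [run_pipeline()].
#' @return Data frame: outcome, formatted `hr_ci` ("HR (lower-upper)"),
#'   printed p, unweighted events, reference group.
#' @export
hr_summary <- function(fits) {
  if (!length(fits))
    return(data.frame(outcome = character(0), hr_ci = character(0),
                      p = character(0), events = integer(0),
                      reference = character(0)))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f))
      return(data.frame(outcome = nm, hr_ci = "unavailable", p = NA_character_,
                        events = NA_integer_, reference = "More Adherent"))
    data.frame(outcome = nm,
               hr_ci = sprintf("%.2f (%.2f-%.2f)", f$hr, f$ci[1], f$ci[2]),
               p = fmt_p(f$p_value), events = f$n_events,
               reference = "More Adherent")
  })
  do.call(rbind, rows)
}

#' Run the full surveillance comparative-effectiveness pipeline
#'
#' simulate (or ingest) -> claims engine -> adherence classification ->
#' boosted-model IPTW -> weighted survival fits -> report tables, with an
#' exclusion ledger accounting for every simulated patient.
#'
#' @param config A [synth_config()]; ignored when `cohort` is supplied.
#' @param seed Seed for simulation and propensity fitting.
#' @param cohort Optional pre-built cohort list (patients, claims) to
#'   analyze instead of simulating.
#' @param outcomes Character vector of [outcome_spec()] names to fit.
#' @param out_dir Optional directory; when given, all tables plus a
#'   manifest JSON (seed, row counts at each exclusion step) are written.
#' @param max_trees Boosting cap passed to [fit_propensity()].
#' @return List: `cohort`, `treatment`, `profiles`, `propensity`
#'   (propensity_fit), `fits`, `descriptives`, `hr_table`, `manifest`.
#' @export
run_pipeline <- function(config = synth_config(), seed = 1L, cohort = NULL,
                         outcomes = c("cancer_specific", "noncancer_specific",
                                      "overall"),
                         out_dir = NULL, max_trees = 5000L) {
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed = seed)
  sums <- summarize_claims(cohort$patients, cohort$claims)
  profiles <- build_profiles(sums$counts, sums$treatment)

  analyzed <- profiles$overall %in% c(LBL_MORE, LBL_LESS)
  pat_a <- cohort$patients[match(profiles$patient_id[analyzed],
                                 cohort$patients$patient_id), ]
  X <- covariate_matrix(pat_a)
  treated <- as.integer(profiles$overall[analyzed] == LBL_MORE)
  prop <- fit_propensity(X, treated, max_trees = max_trees, seed = seed)
  w <- stats::setNames(prop$weights, pat_a$patient_id)

  fits <- list()
  for (nm in outcomes) {
    sp <- outcome_spec(nm)
    tab <- build_outcome(cohort$patients, sums$treatment, profiles, sp,
                         weights = w)
    fits[[nm]] <- weighted_cox(tab)
  }
  desc <- descriptive_table(cohort$patients, sums$treatment, profiles)
  hr_tab <- hr_summary(fits)

  manifest <- list(
    seed = seed,
    n_simulated = nrow(cohort$patients),
    n_no_complete_year = sum(profiles$exclusion_reason == "no_complete_year"),
    n_nonadherent_excluded = sum(profiles$exclusion_reason == "nonadherent"),
    n_analyzed = sum(analyzed),
    n_more_adherent = sum(treated == 1L),
    n_less_adherent = sum(treated == 0L),
    propensity_iterations = prop$best_iteration,
    max_weighted_asmd = max(prop$balance$asmd_treated,
                            prop$balance$asmd_control))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(sums$treatment, file.path(out_dir, "treatment.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient_id = pat_a$patient_id,
                                propensity = prop$e, weight = prop$weights),
                     file.path(out_dir, "weights.csv"), row.names = FALSE)
    utils::write.csv(prop$balance, file.path(out_dir, "balance_weighted.csv"),
                     row.names = FALSE)
    utils::write.csv(prop$balance_unweighted,
                     file.path(out_dir, "balance_unweighted.csv"),
                     row.names = FALSE)
    utils::write.csv(desc$rows, file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(hr_tab, file.path(out_dir, "hazard_ratios.csv"),
                     row.names = FALSE)
    for (nm in names(fits)) {
      cv <- fits[[nm]]$curves
      curve_tab <- do.call(rbind, lapply(names(cv), function(g)
        cbind(group = g, cv[[g]])))
      utils::write.csv(curve_tab,
                       file.path(out_dir, paste0("km_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, treatment = sums$treatment, profiles = profiles,
       propensity = prop, fits = fits, descriptives = desc,
       hr_table = hr_tab, manifest = manifest)
}
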