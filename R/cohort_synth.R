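#' Synthetic administrative-claims cohort generator
#'
#' The real study population (stage II/III colon cancer, ages 66-84,
#' Medicare claims) is access-restricted, so the pipeline is exercised on a
#' synthetic cohort that reproduces the structural features the analysis
#' depends on:
#'
#' * covariate margins close to the published descriptive table of the
#'   study population (age group, race, sex, marital status, diagnosis-year
#'   group, state buy-in, census-tract poverty, urban-rural, region,
#'   substage, grade, tumor site, chemotherapy, individual comorbid
#'   conditions);
#' * *confounding by indication*: a latent surveillance-intensity class
#'   (high/low) whose log-odds depend on prognostic covariates — sicker,
#'   higher-stage patients are tested more;
#' * claims streams: exactly one surgery claim per patient, sequential
#'   chemotherapy courses for chemotherapy recipients (with both the
#'   ≤90-day sequential-claims path and the >6-month cap path occurring),
#'   and per-modality yearly surveillance test counts drawn as Poisson with
#'   intensity-class-specific means, event days uniform within each year so
#'   the 30-day deduplication rule is exercised on clustered dates;
#' * competing cause-specific mortality: independent latent exponential
#'   times for cancer death (driven by stage, grade, chemotherapy and an
#'   independent frailty) and noncancer death (driven by age and comorbid
#'   conditions), observed cause = argmin, with administrative censoring.
#'
#' The generator's treatment variable is the *latent* intensity class; the
#' observed More/Less Adherent label emerges downstream from the claims
#' engine and the classifier, so the generator and the classifier are
#' deliberately decoupled. The true effect of intensity class on the
#' cancer-specific hazard is a config parameter (default 0: surveillance
#' testing does not itself change cancer mortality), which is what the
#' end-to-end weighting recovery tests rely on.
#'
#' @name cohort_synth
NULL

#' Default configuration for the synthetic cohort
#'
#' Margins follow the published study-population distribution; hazard and
#' propensity coefficients are chosen so that roughly two thirds of
#' patients end up More Adherent, about 30% die within 5 years with a
#' cancer/noncancer split resembling the study, and the latent intensity
#' class is strongly confounded with stage, chemotherapy, age and
#' comorbidity.
#'
#' @param n_patients Cohort size.
#' @param true_group_effect_cancer Log hazard ratio of high surveillance
#'   intensity on cancer death (default 0).
#' @param admin_censor_years Administrative censoring horizon in years
#'   after the final treatment date.
#' @param hazard_shape `"exponential"` (default) or `"weibull"`; with
#'   Weibull, `cancer_hazard$shape` / `noncancer_hazard$shape` apply.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 2000L,
                         true_group_effect_cancer = 0,
                         admin_censor_years = 10,
                         hazard_shape = "exponential") {
  stopifnot(n_patients >= 4, admin_censor_years > 0,
            hazard_shape %in% c("exponential", "weibull"))
  structure(list(
    n_patients = as.integer(n_patients),
    covariate_margins = list(
      age_group = c("66-74" = 0.444, "75-79" = 0.291, "80-84" = 0.265),
      race = c(white = 0.846, black = 0.084, asian = 0.033, other = 0.037),
      sex = c(female = 0.558, male = 0.442),
      marital = c(married = 0.548, sep_div = 0.067, single = 0.078,
                  widowed = 0.275, unknown = 0.032),
      dx_year = c("2002-2003" = 0.293, "2004-2006" = 0.378, "2007-2009" = 0.329),
      buyin = c(no = 0.777, yes = 0.223),
      poverty = c(low = 0.268, lower_mid = 0.275, upper_mid = 0.277,
                  high = 0.177, unknown = 0.003),
      urban = c(urban = 0.873, less_urban = 0.103, rural = 0.024),
      region = c(west = 0.361, south = 0.260, northeast = 0.218,
                 midwest = 0.147, pacific = 0.014),
      stage = c(II = 0.560, III = 0.440),
      grade = c(low = 0.763, high = 0.218, unknown = 0.019),
      site = c(proximal = 0.648, distal = 0.352)),
    # marginal probability of each chronic condition flag
    comorbidity_prev = c(diabetes = 0.25, chf = 0.12, copd = 0.18,
                         renal = 0.06, mi = 0.08),
    # P(chemotherapy | stage); adjuvant chemo is far likelier in stage III
    chemo_prob = c(II = 0.22, III = 0.67),
    # log-odds of the high surveillance-intensity latent class; intercept
    # calibrated so about two thirds of analyzed patients are More Adherent
    propensity_coefficients = c(
      intercept = 0.45, age75_79 = -0.35, age80_84 = -0.9,
      stageIII = 0.7, grade_high = 0.35, chemo = 1.2,
      buyin = -0.5, widowed = -0.3, per_comorbidity = -0.25),
    # mean yearly surveillance test counts by latent class (pre-dedup).
    # The classes differ chiefly in imaging/endoscopy: routine CEA blood
    # work is near-universal in both, so completely test-free years (the
    # Nonadherent exclusion path) are rare in either class, while the
    # yearly More/Less label remains a high-fidelity readout of the latent
    # class (per-year misclassification < 5%).
    test_rate_params = list(
      high = c(cea = 4.5, ct = 2.5, scope = 1.5),
      low = c(cea = 4.0, ct = 0.025, scope = 0.015)),
    cancer_hazard = list(
      base_rate = 0.035, shape = 1,
      coef = c(stageIII = 0.9, grade_high = 0.5, chemo = -0.25),
      frailty_sd = 0.2),
    noncancer_hazard = list(
      base_rate = 0.030, shape = 1,
      coef = c(age75_79 = 0.35, age80_84 = 0.8, per_comorbidity = 0.30)),
    true_group_effect_cancer = true_group_effect_cancer,
    admin_censor_years = admin_censor_years,
    hazard_shape = hazard_shape), class = "synth_config")
}

draw_cat <- function(n, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# latent event time with hazard rate * t^(shape-1) * shape (Weibull), via
# inverse transform; shape = 1 reduces to exponential. rate is per year.
draw_time <- function(n, rate_per_year, shape) {
  u <- stats::runif(n)
  365 * (-log(u) / rate_per_year)^(1 / shape)
}

#' Simulate a synthetic patient and claims cohort
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   identical cohorts.
#' @return A list with `patients` (one row per patient: covariates,
#'   `surgery_day`, `death_day` (NA if alive at censoring), `cause`
#'   (`"cancer"`, `"noncancer"` or NA), `censor_day`, `last_followup_day`),
#'   `claims` (patient_id, event_type, service_day), and `truth`
#'   (per-patient latent intensity class and true propensity, plus the
#'   hazard parameters and `true_group_effect_cancer`).
#' @export
simulate_cohort <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_patients
  m <- config$covariate_margins

  pat <- data.frame(patient_id = sprintf("P%05d", seq_len(n)))
  for (v in names(m)) pat[[v]] <- draw_cat(n, m[[v]])
  for (cm in names(config$comorbidity_prev))
    pat[[paste0("cm_", cm)]] <-
      stats::rbinom(n, 1, config$comorbidity_prev[[cm]])
  pat$n_comorbid <- rowSums(pat[paste0("cm_", names(config$comorbidity_prev))])
  pat$chemo <- stats::rbinom(n, 1, config$chemo_prob[pat$stage])

  # latent surveillance-intensity class (confounding by indication)
  pc <- config$propensity_coefficients
  eta <- pc[["intercept"]] +
    pc[["age75_79"]] * (pat$age_group == "75-79") +
    pc[["age80_84"]] * (pat$age_group == "80-84") +
    pc[["stageIII"]] * (pat$stage == "III") +
    pc[["grade_high"]] * (pat$grade == "high") +
    pc[["chemo"]] * pat$chemo +
    pc[["buyin"]] * (pat$buyin == "yes") +
    pc[["widowed"]] * (pat$marital == "widowed") +
    pc[["per_comorbidity"]] * pat$n_comorbid
  p_high <- stats::plogis(eta)
  high <- stats::rbinom(n, 1, p_high)
  if (sum(high) < 2 || sum(1 - high) < 2)
    stop("need at least 2 patients per latent intensity class")

  # treatment claims: one surgery per patient; chemo course for recipients
  pat$surgery_day <- sample(14:45, n, replace = TRUE)
  claims <- data.frame(patient_id = pat$patient_id,
                       event_type = "surgery",
                       service_day = pat$surgery_day)
  final_day <- pat$surgery_day
  chemo_rows <- which(pat$chemo == 1L)
  for (i in chemo_rows) {
    start <- pat$surgery_day[i] + sample(14:60, 1)
    n_cycles <- sample(3:13, 1)
    # mostly biweekly-ish gaps; occasionally a >90-day break so that both
    # the sequential-run rule and the 6-month cap are exercised
    gaps <- sample(c(14:28, 110:150), n_cycles - 1, replace = TRUE,
                   prob = c(rep(0.95 / 15, 15), rep(0.05 / 41, 41)))
    days <- start + c(0, cumsum(gaps))
    claims <- rbind(claims, data.frame(patient_id = pat$patient_id[i],
                                       event_type = "chemo",
                                       service_day = days))
    final_day[i] <- final_treatment_date(pat$surgery_day[i],
                                         days)$final_treatment_day
  }

  # cause-specific latent event times, measured from the final treatment day
  ch <- config$cancer_hazard
  nh <- config$noncancer_hazard
  shape_c <- if (config$hazard_shape == "weibull") ch$shape else 1
  shape_n <- if (config$hazard_shape == "weibull") nh$shape else 1
  frailty <- stats::rnorm(n, 0, ch$frailty_sd)
  log_rate_c <- log(ch$base_rate) +
    ch$coef[["stageIII"]] * (pat$stage == "III") +
    ch$coef[["grade_high"]] * (pat$grade == "high") +
    ch$coef[["chemo"]] * pat$chemo +
    config$true_group_effect_cancer * high + frailty
  log_rate_n <- log(nh$base_rate) +
    nh$coef[["age75_79"]] * (pat$age_group == "75-79") +
    nh$coef[["age80_84"]] * (pat$age_group == "80-84") +
    nh$coef[["per_comorbidity"]] * pat$n_comorbid
  t_cancer <- draw_time(n, exp(log_rate_c), shape_c)
  t_noncancer <- draw_time(n, exp(log_rate_n), shape_n)

  censor_day <- final_day + round(365 * config$admin_censor_years)
  t_min <- pmin(t_cancer, t_noncancer)
  death_day <- final_day + round(t_min)
  died <- death_day < censor_day
  pat$death_day <- ifelse(died, death_day, NA_real_)
  pat$cause <- ifelse(!died, NA_character_,
                      ifelse(t_cancer <= t_noncancer, "cancer", "noncancer"))
  pat$censor_day <- censor_day
  pat$last_followup_day <- pmin(death_day, censor_day)

  # surveillance claims: yearly Poisson counts per modality, days uniform
  # within each post-treatment year, truncated at end of follow-up
  rates <- config$test_rate_params
  modality_type <- c(cea = "CEA", ct = "CT", scope = "colonoscopy")
  sv <- vector("list", 3L * length(modality_type))
  k <- 0L
  for (yr in 1:3) {
    for (mod in names(modality_type)) {
      lam <- ifelse(high == 1L, rates$high[[mod]], rates$low[[mod]])
      cnts <- stats::rpois(n, lam)
      idx <- rep.int(seq_len(n), cnts)
      if (length(idx)) {
        d <- final_day[idx] + 365 * (yr - 1) + floor(stats::runif(length(idx), 0, 365))
        keep <- d <= pat$last_followup_day[idx]
        k <- k + 1L
        sv[[k]] <- data.frame(patient_id = pat$patient_id[idx[keep]],
                              event_type = modality_type[[mod]],
                              service_day = d[keep])
      }
    }
  }
  claims <- rbind(claims, do.call(rbind, sv[seq_len(k)]))
  claims <- claims[order(claims$patient_id, claims$service_day), ]
  rownames(claims) <- NULL

  truth <- list(
    patient = data.frame(patient_id = pat$patient_id,
                         intensity_class = ifelse(high == 1L, "high", "low"),
                         true_propensity = p_high),
    cancer_hazard = ch, noncancer_hazard = nh,
    true_group_effect_cancer = config$true_group_effect_cancer)
  list(patients = pat, claims = claims, truth = truth)
}

#' Write / read a simulated cohort as delimited text + JSON
#'
#' Patient and claims tables are written as CSV (integer day offsets),
#' ground truth as JSON. Round-trips losslessly, including NA death days.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param path Directory to write into (created if needed).
#' @return `write_fixture` returns `path` invisibly; `read_fixture` returns
#'   a cohort list with the same structure as [simulate_cohort()].
#' @export
write_fixture <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(path, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$claims, file.path(path, "claims.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(path, "truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  pfile <- file.path(path, "patients.csv")
  cfile <- file.path(path, "claims.csv")
  for (f in c(pfile, cfile)) if (!file.exists(f)) stop("missing file: ", f)
  patients <- utils::read.csv(pfile, stringsAsFactors = FALSE)
  claims <- utils::read.csv(cfile, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character",
                                           event_type = "character",
                                           service_day = "numeric"))
  bad <- which(!claims$event_type %in% CLAIM_TYPES)
  if (length(bad))
    stop("malformed claims rows (unknown event_type): ",
         paste(head(bad), collapse = ", "))
  truth <- NULL
  tfile <- file.path(path, "truth.json")
  if (file.exists(tfile)) {
    truth <- jsonlite::read_json(tfile, simplifyVector = TRUE)
    truth$patient <- as.data.frame(truth$patient, stringsAsFactors = FALSE)
  }
  list(patients = patients, claims = claims, truth = truth)
}
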