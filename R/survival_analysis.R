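#' IPTW-weighted survival analysis
#'
#' Cause-specific, cause-agnostic and noncancer survival from the final
#' treatment date, under ATE inverse-probability weights. Deaths from
#' causes outside an outcome's event rule are censored at death
#' (cause-specific hazards); all outcomes are administratively censored at
#' the 5-year horizon; the noncancer outcome restricts to years 2-5 via
#' delayed entry (left truncation) at day 365.
#'
#' The weighted Kaplan-Meier and weighted log-rank statistics are computed
#' directly from weighted event and at-risk counts and reduce exactly to
#' their classical forms at unit weights. The weighted Cox model is fit by
#' partial likelihood with case weights (Efron ties, delayed entry) and a
#' robust sandwich variance clustered by patient, via the survival package.
#'
#' @name survival_analysis
NULL

#' Outcome specification
#'
#' @param name One of `"cancer_specific"`, `"noncancer_specific"`,
#'   `"overall"`, or `"colon_cancer_specific"` (definable; in cohorts whose
#'   cancer deaths are not subtyped it coincides with cancer-specific).
#' @param horizon_days Administrative censoring horizon (default 5 years).
#' @return List with `name`, `event_causes`, `entry_day`, `horizon_days`.
#' @export
outcome_spec <- function(name = c("cancer_specific", "noncancer_specific",
                                  "overall", "colon_cancer_specific"),
                         horizon_days = 5 * 365) {
  name <- match.arg(name)
  event_causes <- switch(name,
    cancer_specific = "cancer",
    colon_cancer_specific = "cancer",
    noncancer_specific = "noncancer",
    overall = c("cancer", "noncancer"))
  entry_day <- if (name == "noncancer_specific") 365 else 0
  stopifnot(entry_day < horizon_days)
  list(name = name, event_causes = event_causes,
       entry_day = entry_day, horizon_days = horizon_days)
}

#' Build the analysis table for one outcome
#'
#' Times are days since the final treatment date. Deaths after the horizon
#' and deaths from non-qualifying causes are censored; under delayed entry
#' the patient joins the risk set at `entry_day`.
#'
#' @param patients Patient table (needs `patient_id`, `death_day`, `cause`,
#'   `last_followup_day`).
#' @param treatment Treatment summary with `patient_id`,
#'   `final_treatment_day`.
#' @param profiles Profiles from [build_profiles()]; only non-excluded
#'   patients enter, `group` = 1 for More Adherent.
#' @param spec An [outcome_spec()].
#' @param weights Optional named vector of IPTW weights keyed by
#'   patient_id; default unit weights.
#' @return Data frame: patient_id, entry, time, event (0/1), group (0/1),
#'   weight.
#' @export
build_outcome <- function(patients, treatment, profiles, spec,
                          weights = NULL) {
  keep <- profiles$overall %in% c(LBL_MORE, LBL_LESS)
  prof <- profiles[keep, c("patient_id", "overall")]
  idx <- match(prof$patient_id, patients$patient_id)
  tr <- match(prof$patient_id, treatment$patient_id)
  stopifnot(!anyNA(idx), !anyNA(tr))

  final <- treatment$final_treatment_day[tr]
  t_end <- patients$last_followup_day[idx] - final
  died <- !is.na(patients$death_day[idx])
  cause <- patients$cause[idx]

  event <- died & cause %in% spec$event_causes & t_end <= spec$horizon_days
  time <- pmin(t_end, spec$horizon_days)
  if (any(time < spec$entry_day))
    stop("event or censoring before the entry day violates inclusion logic")
  # follow-up ending exactly at the entry day contributes nothing
  at_entry <- time == spec$entry_day
  prof <- prof[!at_entry, ]
  time <- time[!at_entry]
  event <- event[!at_entry]

  w <- if (is.null(weights)) rep(1, nrow(prof)) else {
    stopifnot(!is.null(names(weights)))
    unname(weights[prof$patient_id])
  }
  if (anyNA(w)) stop("missing weights for some patients")
  data.frame(patient_id = prof$patient_id,
             entry = spec$entry_day, time = time,
             event = as.integer(event),
             group = as.integer(prof$overall == LBL_MORE),
             weight = w)
}

# weighted at-risk and event sums at time t for rows in `idx`
.risk_sums <- function(tab, t) {
  at_risk <- tab$entry < t & tab$time >= t
  dead <- tab$time == t & tab$event == 1L
  c(Y = sum(tab$weight[at_risk]), d = sum(tab$weight[dead]))
}

#' Weighted Kaplan-Meier survivor curve
#'
#' Product-limit estimator with weighted event and at-risk counts,
#' supporting delayed entry. With unit weights it equals the classical
#' Kaplan-Meier estimator; rescaling all weights by a constant leaves the
#' curve unchanged.
#'
#' @param time,event Follow-up time and 0/1 event indicator.
#' @param weight Positive case weights.
#' @param entry Delayed-entry times (default 0).
#' @return Data frame of class `wkm`: time (event times), n_risk, n_event
#'   (weighted sums), surv.
#' @export
weighted_km <- function(time, event, weight = rep(1, length(time)),
                        entry = rep(0, length(time))) {
  stopifnot(all(weight > 0), all(entry < time))
  tab <- data.frame(entry = entry, time = time, event = event, weight = weight)
  if (!any(event == 1L))
    warning("no events; survivor curve is flat at 1")
  tt <- sort(unique(time[event == 1L]))
  surv <- numeric(length(tt))
  s <- 1
  n_risk <- n_event <- numeric(length(tt))
  for (j in seq_along(tt)) {
    rs <- .risk_sums(tab, tt[j])
    n_risk[j] <- rs[["Y"]]
    n_event[j] <- rs[["d"]]
    s <- s * (1 - rs[["d"]] / rs[["Y"]])
    surv[j] <- s
  }
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       surv = surv), class = c("wkm", "data.frame"))
}

#' Weighted log-rank test
#'
#' Score statistic built from weighted event and at-risk counts with the
#' hypergeometric-form variance; at unit weights it reduces exactly to the
#' classical two-group log-rank test.
#'
#' @param time,event,group,weight,entry Columns as in the output of
#'   [build_outcome()]; `group` must take exactly two values.
#' @return List: `statistic` (chi-squared, 1 df), `p_value`, `observed`
#'   and `expected` weighted event totals for the group coded 1.
#' @export
weighted_logrank <- function(time, event, group,
                             weight = rep(1, length(time)),
                             entry = rep(0, length(time))) {
  g <- sort(unique(group))
  if (length(g) != 2) stop("exactly two groups required")
  tab <- data.frame(entry = entry, time = time, event = event,
                    weight = weight, g = as.integer(group == g[2]))
  tt <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in tt) {
    at_risk <- tab$entry < t & tab$time >= t
    dead <- tab$time == t & tab$event == 1L
    Y <- sum(tab$weight[at_risk])
    Y1 <- sum(tab$weight[at_risk & tab$g == 1L])
    d <- sum(tab$weight[dead])
    d1 <- sum(tab$weight[dead & tab$g == 1L])
    if (Y <= 1 || Y1 == 0 || Y1 == Y) next
    O <- O + d1
    E <- E + d * Y1 / Y
    V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Weighted Cox model for the surveillance-group hazard ratio
#'
#' Cox partial likelihood with case weights, Efron tie handling and
#' delayed entry; robust (sandwich) variance clustered by patient gives
#' the confidence interval. The hazard ratio is reported for Less vs.
#' More Adherent (More Adherent is the reference), matching the convention
#' group = 1 for More Adherent in [build_outcome()].
#'
#' @param outcome Data frame from [build_outcome()].
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `survfit_iptw`: `hr`, `ci` (lower, upper),
#'   `log_hr`, `robust_se`, `p_value`, `n_events` (unweighted), `curves`
#'   (weighted KM per group), `fit` (the underlying coxph object).
#' @export
weighted_cox <- function(outcome, conf_level = 0.95) {
  stopifnot(all(c("entry", "time", "event", "group", "weight") %in% names(outcome)))
  if (!all(tapply(outcome$event, outcome$group, sum) >= 1))
    stop("both groups need at least one event")
  # covariate = Less Adherent indicator, so the HR is Less vs. More
  outcome$less <- 1L - outcome$group
  fit <- survival::coxph(
    survival::Surv(entry, time, event) ~ less,
    data = outcome, weights = outcome$weight, id = outcome$patient_id,
    ties = "efron", robust = TRUE)
  if (!is.null(fit$info) && isTRUE(fit$fail)) stop("Cox model did not converge")
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])  # robust variance when robust = TRUE
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  curves <- lapply(split(outcome, outcome$group), function(d)
    weighted_km(d$time, d$event, d$weight, d$entry))
  names(curves) <- ifelse(names(curves) == "1", "more_adherent", "less_adherent")
  structure(list(
    hr = exp(b), ci = exp(b + c(-1, 1) * z * se),
    log_hr = b, robust_se = se,
    p_value = 2 * stats::pnorm(-abs(b / se)),
    n_events = sum(outcome$event), curves = curves, fit = fit),
    class = "survfit_iptw")
}

#' @export
print.survfit_iptw <- function(x, ...) {
  cat(sprintf("IPTW Cox: HR (Less vs More) %.2f (%.2f-%.2f), p = %s; events = %d\n",
              x$hr, x$ci[1], x$ci[2], format.pval(x$p_value, digits = 3),
              x$n_events))
  invisible(x)
}

#' Proportional-hazards diagnostics
#'
#' Returns the log(-log) survivor transforms of the two weighted group
#' curves (parallel curves support proportionality; under PH their
#' vertical offset is the log hazard ratio) and a Wald test of the
#' group-by-log(time) interaction from an episode-split weighted Cox
#' model.
#'
#' @param outcome Data frame from [build_outcome()].
#' @return List: `cloglog` (per group: time, log_time, cloglog),
#'   `interaction` (coef, se, z, p for the group x log(time) term).
#' @export
ph_check <- function(outcome) {
  outcome$less <- 1L - outcome$group
  cuts <- sort(unique(outcome$time[outcome$event == 1L]))
  # episode-split at event times (counting-process form, respects entry)
  long <- do.call(rbind, lapply(seq_len(nrow(outcome)), function(i) {
    r <- outcome[i, ]
    b <- sort(unique(c(r$entry, cuts[cuts > r$entry & cuts < r$time], r$time)))
    data.frame(patient_id = r$patient_id, tstart = b[-length(b)],
               tstop = b[-1L],
               ev = c(rep(0L, length(b) - 2L), r$event),
               less = r$less, weight = r$weight)
  }))
  long$logt <- log(long$tstop)
  fit <- survival::coxph(
    survival::Surv(tstart, tstop, ev) ~ less + less:logt,
    data = long, weights = long$weight, id = long$patient_id,
    ties = "efron", robust = TRUE)
  i <- grep("logt", names(stats::coef(fit)))
  b <- stats::coef(fit)[i]
  se <- sqrt(diag(fit$var))[i]
  curves <- lapply(split(outcome, outcome$group), function(d)
    weighted_km(d$time, d$event, d$weight, d$entry))
  cloglog <- lapply(curves, function(cv) {
    ok <- cv$surv > 0 & cv$surv < 1
    data.frame(time = cv$time[ok], log_time = log(cv$time[ok]),
               cloglog = log(-log(cv$surv[ok])))
  })
  names(cloglog) <- ifelse(names(cloglog) == "1", "more_adherent",
                           "less_adherent")
  list(cloglog = cloglog,
       interaction = list(coef = unname(b), se = unname(se),
                          z = unname(b / se),
                          p = unname(2 * stats::pnorm(-abs(b / se)))))
}

#' Quantile read-off from a survivor curve
#'
#' The q-quantile is the smallest observed event time at which the
#' survivor curve has dropped to 1-q or below; NA ("not reached") if the
#' curve never gets there.
#'
#' @param curve A `wkm` curve from [weighted_km()].
#' @param q Quantile in (0,1); 0.5 for the median, 0.25 for the 25% event
#'   time.
#' @return Time, or NA if not reached.
#' @export
km_quantile <- function(curve, q) {
  if (q <= 0 || q >= 1) stop("q must lie strictly in (0,1)")
  hit <- which(curve$surv <= 1 - q)
  if (!length(hit)) return(NA_real_)
  curve$time[hit[1L]]
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Censoring is treated as the event and deaths are censored; the median
#' of the resulting curve estimates the median potential follow-up time.
#'
#' @param time Follow-up times.
#' @param event 0/1 death indicator (1 = death, i.e. censored in reverse).
#' @param weight Optional case weights.
#' @return Median follow-up time (same units as `time`), NA if not reached.
#' @export
median_followup <- function(time, event, weight = rep(1, length(time))) {
  rev_curve <- weighted_km(time, 1L - event, weight)
  km_quantile(rev_curve, 0.5)
}
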