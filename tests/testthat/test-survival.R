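test_that("outcome tables censor by cause and horizon", {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    death_day = c(1000, 1000, 2200, NA),
    cause = c("cancer", "noncancer", "cancer", NA),
    last_followup_day = c(1000, 1000, 2200, 3750))
  treatment <- data.frame(patient_id = c("A", "B", "C", "D"),
                          final_treatment_day = 100)
  profiles <- data.frame(patient_id = c("A", "B", "C", "D"),
                         overall = c("MORE", "LESS", "MORE", "EXCLUDED"))
  ov <- build_outcome(patients, treatment, profiles, outcome_spec("overall"))
  expect_equal(nrow(ov), 3)  # excluded patient dropped
  expect_equal(ov$time[ov$patient_id == "A"], 900)
  expect_equal(ov$event[ov$patient_id == "A"], 1L)
  # death past the 5-year horizon is censored at 1825
  expect_equal(ov$time[ov$patient_id == "C"], 1825)
  expect_equal(ov$event[ov$patient_id == "C"], 0L)
  cs <- build_outcome(patients, treatment, profiles, outcome_spec("cancer_specific"))
  expect_equal(cs$event[cs$patient_id == "A"], 1L)
  expect_equal(cs$event[cs$patient_id == "B"], 0L)  # other cause: censored
  nc <- build_outcome(patients, treatment, profiles, outcome_spec("noncancer_specific"))
  expect_true(all(nc$entry == 365))
  expect_equal(nc$event[nc$patient_id == "B"], 1L)
  expect_equal(nc$event[nc$patient_id == "A"], 0L)
  # weights are matched by patient id
  w <- c(A = 2, B = 3, C = 1.5, D = 9)
  ovw <- build_outcome(patients, treatment, profiles, outcome_spec("overall"),
                       weights = w)
  expect_equal(ovw$weight, unname(w[ovw$patient_id]))
})

test_that("weighted KM equals a hand-computed table at unit weights", {
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 0, 1)
  km <- weighted_km(time, event)
  expect_equal(km$time, c(1, 2, 3, 5))
  expect_equal(km$surv, c(5 / 6, 4 / 6, 4 / 9, 0))
  expect_equal(km$n_risk, c(6, 5, 3, 1))
  # scale invariance of the product-limit ratio
  km2 <- weighted_km(time, event, weight = rep(7, 6))
  expect_equal(km2$surv, km$surv)
  # single patient: one step from 1 to 0
  km3 <- weighted_km(5, 1)
  expect_equal(km3$surv, 0)
  expect_warning(weighted_km(c(1, 2), c(0, 0)), "no events")
})

test_that("weighted KM matches the classical estimator on random data", {
  for (s in 1:5) {
    tab <- random_outcome(150, seed = s)
    km <- weighted_km(tab$time, tab$event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = tab)
    ref <- summary(sf, times = km$time)$surv
    expect_lt(max(abs(km$surv - ref)), 1e-8)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("weighted KM supports delayed entry", {
  tab <- random_outcome(200, seed = 30, entry = 2)
  km <- weighted_km(tab$time, tab$event, entry = tab$entry)
  sf <- survival::survfit(survival::Surv(entry, time, event) ~ 1, data = tab)
  ref <- summary(sf, times = km$time)$surv
  expect_lt(max(abs(km$surv - ref)), 1e-8)
})

test_that("weighted log-rank reduces to the classical test at unit weights", {
  for (s in 1:5) {
    tab <- random_outcome(180, seed = 10 + s)
    lr <- weighted_logrank(tab$time, tab$event, tab$group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group, data = tab)
    expect_lt(abs(lr$statistic - ref$chisq), 1e-8)
  }
  # identical groups: statistic 0, p 1 (duplicate every subject in both arms)
  base <- random_outcome(60, seed = 77)
  dup <- rbind(transform(base, group = 0), transform(base, group = 1))
  lr0 <- weighted_logrank(dup$time, dup$event, dup$group)
  expect_lt(lr0$statistic, 1e-10)
  expect_gt(lr0$p_value, 0.999)
  expect_error(weighted_logrank(base$time, base$event, rep(1, 60)), "two groups")
})

test_that("the log-rank test detects a strong hazard difference", {
  set.seed(91)
  rejections <- sapply(1:20, function(i) {
    n <- 2000
    g <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * 2^g)
    ev <- as.integer(t < 5)
    weighted_logrank(pmin(t, 5), ev, g)$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})

test_that("weighted Cox matches the reference fit and inverts under relabeling", {
  tab <- random_outcome(200, seed = 55, weighted = TRUE)
  fit <- weighted_cox(tab)
  ref <- survival::coxph(survival::Surv(time, event) ~ I(1 - group),
                         data = tab, weights = tab$weight,
                         id = tab$patient_id, ties = "efron", robust = TRUE)
  expect_lt(abs(fit$log_hr - unname(coef(ref)[1])), 1e-6)
  expect_lt(abs(fit$robust_se - sqrt(ref$var[1, 1])), 1e-6)
  expect_true(fit$ci[1] <= fit$hr && fit$hr <= fit$ci[2])
  # swapping group labels inverts the hazard ratio exactly
  swapped <- transform(tab, group = 1L - group)
  fit2 <- weighted_cox(swapped)
  expect_equal(fit2$log_hr, -fit$log_hr, tolerance = 1e-8)
  # curves are attached per group
  expect_named(fit$curves, c("less_adherent", "more_adherent"))
  bad <- transform(tab, event = ifelse(group == 1, 0L, event))
  expect_error(weighted_cox(bad), "at least one event")
})

test_that("proportional-hazards diagnostics behave under PH and crossing", {
  # under proportional hazards the cloglog curves are parallel with offset log HR
  set.seed(61)
  n <- 3000
  g <- rbinom(n, 1, 0.5)
  hr <- 1.8
  t <- rexp(n, 0.12 * hr^(1 - g))  # group 0 = "less", higher hazard
  tab <- data.frame(patient_id = as.character(1:n), entry = 0,
                    time = pmin(t, 5), event = as.integer(t < 5),
                    group = g, weight = 1)
  d <- ph_check(tab)
  m <- d$cloglog$more_adherent
  l <- d$cloglog$less_adherent
  off <- sapply(c(1, 2, 3), function(tt) {
    approx(l$time, l$cloglog, tt)$y - approx(m$time, m$cloglog, tt)$y
  })
  expect_lt(max(abs(off - log(hr))), 0.25)
  expect_gt(d$interaction$p, 0.01)  # no spurious violation signal

  # crossing hazards: interaction with log(time) must fire
  set.seed(62)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  shape <- ifelse(g == 1, 0.6, 1.8)  # one decreasing, one increasing hazard
  t <- rweibull(n, shape = shape, scale = 6)
  tab2 <- data.frame(patient_id = as.character(1:n), entry = 0,
                     time = pmin(t, 5), event = as.integer(t < 5),
                     group = g, weight = 1)
  d2 <- ph_check(tab2)
  expect_lt(d2$interaction$p, 0.05)
})

test_that("KM quantiles and reverse-KM follow-up read off correctly", {
  curve <- structure(data.frame(time = c(5.3, 8), n_risk = c(10, 4),
                                n_event = c(3, 1), surv = c(0.74, 0.5)),
                     class = c("wkm", "data.frame"))
  expect_equal(km_quantile(curve, 0.25), 5.3)
  expect_equal(km_quantile(curve, 0.5), 8)
  floor_curve <- transform(curve, surv = c(0.95, 0.9))
  expect_true(is.na(km_quantile(floor_curve, 0.25)))
  expect_error(km_quantile(curve, 1.2), "strictly")
  # fully followed cohort: reverse-KM median equals the administrative horizon
  time <- c(rep(10, 6), 3, 4)       # 6 administratively censored, 2 deaths
  event <- c(rep(0, 6), 1, 1)
  expect_equal(median_followup(time, event), 10)
})
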