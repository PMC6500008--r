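test_that("simulation is seed-deterministic", {
  cfg <- synth_config(300)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$claims, c$claims))
})

test_that("ground truth passes the configured effect through", {
  cfg <- synth_config(200, true_group_effect_cancer = 0)
  expect_equal(simulate_cohort(cfg, seed = 1)$truth$true_group_effect_cancer, 0)
  cfg2 <- synth_config(200, true_group_effect_cancer = -0.3)
  expect_equal(simulate_cohort(cfg2, seed = 1)$truth$true_group_effect_cancer, -0.3)
})

test_that("null propensity coefficients give the intercept-implied class split", {
  cfg <- synth_config(5000)
  ic <- 0.4
  cfg$propensity_coefficients[] <- 0
  cfg$propensity_coefficients[["intercept"]] <- ic
  co <- simulate_cohort(cfg, seed = 3)
  p <- stats::plogis(ic)
  frac <- mean(co$truth$patient$intensity_class == "high")
  expect_true(all(co$truth$patient$true_propensity == p))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5000))
})

test_that("covariate margins are honored", {
  cfg <- synth_config(2000)
  co <- simulate_cohort(cfg, seed = 4)
  p2 <- cfg$covariate_margins$stage[["II"]]
  frac <- mean(co$patients$stage == "II")
  expect_lt(abs(frac - p2), 3 * sqrt(p2 * (1 - p2) / 2000))
  pf <- cfg$covariate_margins$sex[["female"]]
  expect_lt(abs(mean(co$patients$sex == "female") - pf),
            3 * sqrt(pf * (1 - pf) / 2000))
  expect_true(all(co$truth$patient$true_propensity > 0 &
                    co$truth$patient$true_propensity < 1))
})

test_that("event ordering and treatment-claim structure hold", {
  co <- simulate_cohort(synth_config(500), seed = 9)
  surg <- co$claims[co$claims$event_type == "surgery", ]
  expect_equal(nrow(surg), 500)
  expect_equal(sort(surg$patient_id), sort(co$patients$patient_id))
  # no claim precedes the patient's surgery
  first_claim <- tapply(co$claims$service_day, co$claims$patient_id, min)
  expect_true(all(first_claim == co$patients$surgery_day[
    match(names(first_claim), co$patients$patient_id)]))
  # chemo starts 14-60 days post surgery
  chemo_first <- tapply(co$claims$service_day[co$claims$event_type == "chemo"],
                        co$claims$patient_id[co$claims$event_type == "chemo"], min)
  lag <- chemo_first - co$patients$surgery_day[
    match(names(chemo_first), co$patients$patient_id)]
  expect_true(all(lag >= 14 & lag <= 60))
  # no death precedes the final treatment date
  sums <- summarize_claims(co$patients, co$claims)
  dead <- !is.na(co$patients$death_day)
  expect_true(all(co$patients$death_day[dead] >=
                    sums$treatment$final_treatment_day[dead]))
  # both chemo anchoring paths occur: capped courses and uncapped runs
  chemo_pat <- sums$treatment[sums$treatment$modality == "surgery_plus_chemo", ]
  starts <- chemo_first[chemo_pat$patient_id]
  span <- chemo_pat$final_treatment_day - starts
  expect_true(any(span == 183))   # 6-month cap engaged
  expect_true(any(span > 0 & span < 183))  # plain sequential run
})

test_that("refuses degenerate intensity-class splits", {
  cfg <- synth_config(50)
  cfg$propensity_coefficients[] <- 0
  cfg$propensity_coefficients[["intercept"]] <- 20  # everyone high
  expect_error(simulate_cohort(cfg, seed = 2), "at least 2 patients")
})

test_that("fixtures round-trip losslessly through text files", {
  co <- simulate_cohort(synth_config(60), seed = 12)
  dir <- tempfile("fixture")
  write_fixture(co, dir)
  back <- read_fixture(dir)
  expect_equal(back$patients, co$patients)
  expect_equal(back$claims, co$claims)
  expect_equal(back$truth$patient$true_propensity,
               co$truth$patient$true_propensity)
  expect_equal(back$truth$true_group_effect_cancer,
               co$truth$true_group_effect_cancer)
  # integer day offsets survive exactly
  expect_identical(back$claims$service_day, co$claims$service_day)

  # empty claims table round-trips
  co$claims <- co$claims[0, ]
  dir2 <- tempfile("fixture")
  write_fixture(co, dir2)
  expect_equal(nrow(read_fixture(dir2)$claims), 0)
  expect_error(read_fixture(tempfile()), "missing file")
})

test_that("confounding by indication is real in the default cohort", {
  # unweighted association between latent class and cancer death differs
  # from the configured null effect
  co <- simulate_cohort(synth_config(5000), seed = 21)
  sums <- summarize_claims(co$patients, co$claims)
  cls <- co$truth$patient$intensity_class
  t_days <- co$patients$last_followup_day - sums$treatment$final_treatment_day
  ev <- as.integer(!is.na(co$patients$death_day) &
                     co$patients$cause == "cancer" & t_days <= 1825)
  fit <- survival::coxph(survival::Surv(pmin(t_days, 1825), ev) ~ I(cls == "low"))
  z <- abs(coef(fit) / sqrt(fit$var[1, 1]))
  expect_gt(z, 2)  # detectable at n = 5000
})
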