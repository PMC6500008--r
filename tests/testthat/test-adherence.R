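label_rank <- function(l) match(l, c("NONADHERENT", "LESS", "MORE"))

test_that("yearly classification reproduces the published scheme", {
  # full adherence
  expect_equal(classify_year(1, 2, 1, 1), "MORE")
  # no tests at all
  expect_equal(classify_year(1, 0, 0, 0), "NONADHERENT")
  # CEA only, however many
  expect_equal(classify_year(1, 3, 0, 0), "LESS")
  # single-modality Less rows
  expect_equal(classify_year(1, 1, 0, 0), "LESS")
  expect_equal(classify_year(1, 0, 2, 0), "LESS")
  expect_equal(classify_year(1, 0, 0, 1), "LESS")
  # partial CEA with a second modality is still More
  expect_equal(classify_year(1, 1, 1, 0), "MORE")
  expect_equal(classify_year(1, 1, 0, 1), "MORE")
  expect_equal(classify_year(1, 2, 1, 0), "MORE")
  expect_equal(classify_year(1, 2, 0, 1), "MORE")
  expect_error(classify_year(1, -1, 0, 0), "nonnegative")
})

test_that("a prior-year colonoscopy carries over into years 2 and 3", {
  # zero current-year tests with carry-over: one active modality -> LESS
  expect_equal(classify_year(2, 0, 0, 0, prior_year_scope_count = 1), "LESS")
  expect_equal(classify_year(3, 0, 0, 0, prior_year_scope_count = 2), "LESS")
  # carry-over contributes the second active modality
  expect_equal(classify_year(2, 2, 0, 0, prior_year_scope_count = 1), "MORE")
  expect_equal(classify_year(2, 0, 1, 0, prior_year_scope_count = 1), "MORE")
  # no carry-over into year 1
  expect_equal(classify_year(1, 0, 0, 0, prior_year_scope_count = 5), "NONADHERENT")
  # carry-over can be disabled
  rules <- rule_table(carry_over = FALSE)
  expect_equal(classify_year(2, 0, 0, 0, prior_year_scope_count = 1,
                             rules = rules), "NONADHERENT")
})

test_that("classification is total and monotone over the count lattice", {
  for (yr in 1:3) {
    for (cea in 0:5) for (ct in 0:5) for (scope in 0:5) for (prior in 0:1) {
      lab <- classify_year(yr, cea, ct, scope, prior)
      expect_true(lab %in% c("MORE", "LESS", "NONADHERENT"))
      # adding one test to any modality never demotes the label
      for (bump in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        lab2 <- classify_year(yr, cea + bump[1], ct + bump[2],
                              scope + bump[3], prior)
        expect_gte(label_rank(lab2), label_rank(lab))
      }
    }
  }
})

test_that("explicit rule-table overrides supersede the canonical rule", {
  ov <- data.frame(year = 1, cea_cat = "0", ct_cat = "1+", scope_cat = "1+",
                   carry = FALSE, label = "LESS")
  rules <- rule_table(overrides = ov)
  expect_equal(classify_year(1, 0, 1, 1), "MORE")                 # canonical
  expect_equal(classify_year(1, 0, 1, 1, rules = rules), "LESS")  # overridden
  expect_equal(classify_year(1, 2, 1, 1, rules = rules), "MORE")  # untouched
})

test_that("overall classification combines yearly labels by strict majority", {
  expect_equal(classify_overall("MORE"), "MORE")
  expect_equal(classify_overall("LESS"), "LESS")
  expect_equal(classify_overall(character(0)), "EXCLUDED")
  expect_equal(classify_overall(rep("NONADHERENT", 3)), "EXCLUDED")
  expect_equal(classify_overall("NONADHERENT"), "EXCLUDED")
  expect_equal(classify_overall(c("MORE", "LESS")), "LESS")         # tie
  expect_equal(classify_overall(c("MORE", "MORE", "LESS")), "MORE") # majority
  expect_equal(classify_overall(c("MORE", "MORE")), "MORE")
  # a single Nonadherent year inside tested follow-up counts as Less
  expect_equal(classify_overall(c("MORE", "NONADHERENT")), "LESS")
  expect_equal(classify_overall(c("MORE", "MORE", "NONADHERENT")), "MORE")
  # depends only on label counts, not their order
  expect_equal(classify_overall(c("LESS", "MORE", "MORE")),
               classify_overall(c("MORE", "MORE", "LESS")))
  # combination rule is configurable
  any_more <- function(n_more, n_less) n_more >= 1
  expect_equal(classify_overall(c("MORE", "LESS"), more_if = any_more), "MORE")
})

test_that("profiles reproduce a per-patient reclassification oracle", {
  set.seed(42)
  n <- 120
  counts <- data.frame(patient_id = sprintf("Q%03d", 1:n))
  for (m in c("cea", "ct", "scope")) for (k in 1:3)
    counts[[paste0(m, "_", k)]] <- rpois(n, 0.8)
  treatment <- data.frame(patient_id = counts$patient_id,
                          complete_years = sample(0:3, n, replace = TRUE))
  prof <- build_profiles(counts, treatment)
  for (i in seq_len(n)) {
    ny <- treatment$complete_years[i]
    labs <- character(0)
    for (k in seq_len(ny))
      labs[k] <- classify_year(k, counts[[paste0("cea_", k)]][i],
                               counts[[paste0("ct_", k)]][i],
                               counts[[paste0("scope_", k)]][i],
                               if (k > 1) counts[[paste0("scope_", k - 1)]][i] else 0)
    expect_equal(prof$overall[i], classify_overall(labs))
  }
  # labelled years line up with completeness
  expect_true(all(is.na(prof$year2[treatment$complete_years < 2])))
  expect_error(build_profiles(counts, treatment[-1, ]), "missing completeness")
})

test_that("degenerate cohorts classify as expected", {
  n <- 10
  counts <- data.frame(patient_id = sprintf("R%02d", 1:n),
                       cea_1 = 2, cea_2 = 2, cea_3 = 2,
                       ct_1 = 1, ct_2 = 1, ct_3 = 1,
                       scope_1 = 1, scope_2 = 1, scope_3 = 1)
  treatment <- data.frame(patient_id = counts$patient_id, complete_years = 3L)
  prof <- build_profiles(counts, treatment)
  expect_true(all(prof$overall == "MORE"))
  zero <- counts
  zero[, -1] <- 0
  prof0 <- build_profiles(zero, treatment)
  expect_true(all(prof0$overall == "EXCLUDED"))
  expect_true(all(prof0$exclusion_reason == "nonadherent"))
  freq <- label_frequencies(prof0)
  expect_equal(unname(freq[["EXCLUDED"]]), n)
})
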