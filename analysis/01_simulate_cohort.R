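#!/usr/bin/env Rscript
# Simulate the synthetic stage II/III colon cancer claims cohort that the
# downstream analyses run on, and persist it as plain-text fixtures.
#
# The generator builds in the two features the study design has to cope
# with: confounding by indication (a latent surveillance-intensity class
# driven by stage, grade, chemotherapy, age, comorbidity) and competing
# cause-specific mortality. The true effect of surveillance intensity on
# cancer death is zero, so any association the analysis finds is either
# confounding or estimator bias.

library(colonsurv)

seed <- 20260925L
cfg <- synth_config(n_patients = 2000)
cohort <- simulate_cohort(cfg, seed = seed)

dir.create("results", showWarnings = FALSE)
write_fixture(cohort, "results/cohort")

cat("Simulated", nrow(cohort$patients), "patients,",
    nrow(cohort$claims), "claims (seed", seed, ")\n")
cat("Latent high-intensity class:",
    sum(cohort$truth$patient$intensity_class == "high"), "patients\n")
cat("Deaths observed:", sum(!is.na(cohort$patients$death_day)),
    "( cancer:", sum(cohort$patients$cause == "cancer", na.rm = TRUE),
    "/ noncancer:", sum(cohort$patients$cause == "noncancer", na.rm = TRUE),
    ")\n")
cat("Fixtures written under results/cohort/\n")
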