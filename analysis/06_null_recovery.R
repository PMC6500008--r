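#!/usr/bin/env Rscript
# The methodological point of the pipeline, as a simulation experiment:
# with a true null effect of surveillance intensity on cancer death, the
# unweighted hazard ratio is biased by confounding by indication while the
# IPTW estimate recovers the null at close to nominal CI coverage.
# Replicates the full pipeline (simulate -> classify -> weight -> fit) on
# independent cohorts.

library(colonsurv)

study <- recovery_study(n_reps = 50, n_patients = 2000, seed_base = 50000L)

write.csv(study$results, "results/null_recovery.csv", row.names = FALSE)

cat(sprintf("Replicates: %d (n = 2000 each, true cancer log-HR = 0)\n",
            nrow(study$results)))
cat(sprintf("IPTW 95%% CI coverage of HR = 1: %.0f%%\n", 100 * study$coverage))
cat(sprintf("Mean log-HR  IPTW: %+.3f   unweighted: %+.3f\n",
            study$bias_iptw, study$bias_unweighted))
cat(sprintf("Absolute-bias ratio (unweighted / IPTW): %.1f\n",
            study$bias_ratio))
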