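#!/usr/bin/env Rscript
# Turn the raw claims stream into surveillance-adherence classifications:
# anchor follow-up at the final treatment date, deduplicate tests with the
# 30-day rule, count CEA / CT-or-PET / colonoscopy per follow-up year, and
# label each patient More Adherent, Less Adherent, or excluded.

library(colonsurv)

cohort <- read_fixture("results/cohort")
sums <- summarize_claims(cohort$patients, cohort$claims)
profiles <- build_profiles(sums$counts, sums$treatment)

write.csv(sums$treatment, "results/treatment_summary.csv", row.names = FALSE)
write.csv(profiles, "results/surveillance_profiles.csv", row.names = FALSE)

freq <- label_frequencies(profiles)
n <- nrow(profiles)
cat("Overall surveillance classification of", n, "patients:\n")
for (l in names(freq))
  cat(sprintf("  %-12s %5d (%.1f%%)\n", l, freq[[l]], 100 * freq[[l]] / n))
cat("Exclusions: no complete follow-up year:",
    sum(profiles$exclusion_reason == "no_complete_year"),
    "; no surveillance tests at all:",
    sum(profiles$exclusion_reason == "nonadherent"), "\n")
cat("Chemotherapy anchoring: ",
    sum(sums$treatment$modality == "surgery_plus_chemo"),
    "patients anchored at end of sequential chemotherapy\n")
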