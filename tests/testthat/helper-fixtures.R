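# small in-code fixtures shared across tests

# brute-force deduplication oracle: among all subsets whose consecutive
# gaps are >= min_gap, take the maximum-cardinality one, breaking ties by
# earliest elements (lexicographic). Independent of the greedy scan.
dedupe_oracle <- function(days, min_gap = 30) {
  n <- length(days)
  if (n == 0L) return(numeric(0))
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    sub <- days[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sub) > 1 && any(diff(sub) < min_gap)) next
    if (is.null(best) || length(sub) > length(best)) best <- sub
    else if (length(sub) == length(best)) {
      cmp <- sub - best
      first <- which(cmp != 0)[1]
      if (!is.na(first) && cmp[first] < 0) best <- sub
    }
  }
  best
}

# hand-sized outcome table generator for survival tests
random_outcome <- function(n, seed, weighted = FALSE, entry = 0) {
  set.seed(seed)
  time <- round(rexp(n, 0.15), 2) + entry + 0.01
  data.frame(patient_id = sprintf("S%03d", seq_len(n)),
             entry = entry,
             time = time,
             event = rbinom(n, 1, 0.7),
             group = rbinom(n, 1, 0.5),
             weight = if (weighted) round(runif(n, 0.4, 2.5), 3) else 1)
}

# tiny cohort whose claims exercise every engine path
toy_cohort <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    last_followup_day = c(1200, 400, 2000))
  claims <- data.frame(
    patient_id = c("A", "A", "A", "A", "A", "A",
                   "B", "B",
                   "C", "C", "C", "C"),
    event_type = c("surgery", "chemo", "chemo", "CEA", "CEA", "CT",
                   "surgery", "colonoscopy",
                   "surgery", "CEA", "PET", "colonoscopy"),
    service_day = c(10, 40, 100, 150, 200, 210,
                    20, 300,
                    5, 100, 120, 400))
  list(patients = patients, claims = claims)
}
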