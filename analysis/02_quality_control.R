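#!/usr/bin/env Rscript
# Stage 2 — triplet classification and quality control.
#
# Classifies every trial as the third element of a high- or
# low-probability triplet, applies the trial-level exclusions
# (incorrect, trill, repetition, RT > 1000 ms) and the participant-level
# rules (accuracy >= 80%, block-start latency <= 1500 ms in fewer than 5
# blocks, mean first-trial RT <= 1000 ms, age <= 35), and writes an
# auditable exclusion report.

suppressPackageStartupMessages(library(asrtlearn))

loaded <- read_trials("results/data/trials.csv")
stopifnot(nrow(loaded$rejects) == 0L)
cat("Classifying and flagging", nrow(loaded$trials), "trials ...\n")
flagged <- flag_trials(classify_triplets(loaded$trials))

qc <- apply_qc(flagged)
report <- build_exclusion_report(flagged, qc$participants)
print(report)

jsonlite::write_json(
  list(n_trials = report$n_trials, by_reason = report$by_reason,
       total_excluded = report$total_excluded,
       pct_excluded = report$pct_excluded,
       participants = report$participants),
  "results/exclusion_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)
readr::write_csv(qc$trials, "results/data/trials_flagged.csv")
cat(sprintf("-> kept %d of %d participants\n",
            sum(qc$participants$kept), nrow(qc$participants)))
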