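#!/usr/bin/env Rscript
# Stage 4 — online/offline decomposition of learning dynamics.
#
# Each 80-trial block is cut into five 16-trial bins. Online change =
# last-bin minus first-bin score within a block (25 per participant);
# offline change = next block's first bin minus previous block's last
# bin (24 per participant); computed for the statistical learning score
# and the bin median RT (general skill). Group-level one-sample t tests
# ask whether learning happened online (positive) and/or offline
# (negative = forgetting), and a mixed ANOVA compares phases across
# groups.

suppressPackageStartupMessages(library(asrtlearn))

flagged <- readr::read_csv("results/data/trials_flagged.csv",
                           show_col_types = FALSE, progress = FALSE)
bins <- bin_scores(flagged)
changes <- change_scores(bins)
readr::write_csv(changes, "results/changes.csv")
cm <- mean_change_scores(changes)
readr::write_csv(cm, "results/change_means.csv")

summary_tab <- summarize_changes(changes)
cat("Change-score summary (one-sample t vs 0):\n")
print(summary_tab, n = Inf)

long <- tidyr::pivot_longer(
  cm, dplyr::starts_with("mean_"),
  names_to = c("phase", "measure"), names_pattern = "mean_(.*)_(.*)",
  values_to = "value"
)
anovas <- list()
for (m in c("sl", "gs")) {
  sub <- long[long$measure == m & !is.na(long$value), ]
  anovas[[m]] <- mixed_anova(sub, "value", "phase", "group",
                             "participant_id")
  cat(sprintf("\nPhase x group ANOVA (%s):\n",
              if (m == "sl") "statistical learning" else "general skill"))
  print(anovas[[m]])
}

jsonlite::write_json(
  list(summary = summary_tab, anova_sl = anovas$sl, anova_gs = anovas$gs),
  "results/change_anovas.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)
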