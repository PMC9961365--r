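#!/usr/bin/env Rscript
# Stage 5 — process dissociation procedure (generation task).
#
# Each kept participant generates 4 inclusion and 4 exclusion runs of 24
# presses. Runs dominated (> 50%) by trills/repetitions are removed; the
# remaining presses are scored as the percentage closing a
# high-probability triplet under the participant's own sequence, and
# compared with the 25% chance level per group and condition. Ratios
# above chance under exclusion instructions indicate implicit knowledge.

suppressPackageStartupMessages(library(asrtlearn))

cfg <- read_run_config("results/data/config.json")
flagged <- readr::read_csv("results/data/trials_flagged.csv",
                           show_col_types = FALSE, progress = FALSE)
parts <- readr::read_csv("results/data/participants.csv",
                         show_col_types = FALSE, progress = FALSE)
kept_parts <- parts[parts$participant_id %in%
                      unique(flagged$participant_id), ]

presses <- simulate_pdp_cohort(
  kept_parts,
  bias_inclusion = cfg$pdp_bias_inclusion,
  bias_exclusion = cfg$pdp_bias_exclusion,
  n_runs = cfg$pdp_n_runs,
  seed = cfg$seed + 1L
)
readr::write_csv(presses, "results/data/pdp_presses.csv")

ratios <- pdp_ratios(presses, kept_parts)
readr::write_csv(ratios, "results/pdp_ratios.csv")

tests <- list()
for (g in unique(ratios$group)) {
  for (cond in c("inclusion", "exclusion")) {
    r <- ratios$ratio[ratios$group == g & ratios$condition == cond]
    tt <- chance_test(r, chance = 25)
    tests[[paste(g, cond, sep = "_")]] <-
      list(t = tt$t, df = tt$df, p = tt$p, mean = tt$mean, sd = tt$sd,
           n = tt$n)
    cat(sprintf("%-12s %-9s mean %.1f%%  t(%d) = %.2f, p = %.2g\n",
                g, cond, tt$mean, tt$df, tt$t, tt$p))
  }
}

wide <- tidyr::pivot_wider(
  ratios[, c("participant_id", "group", "condition", "ratio")],
  names_from = "condition", values_from = "ratio"
)
wide <- wide[stats::complete.cases(wide), ]
long <- tidyr::pivot_longer(wide, c("inclusion", "exclusion"),
                            names_to = "condition", values_to = "ratio")
an <- mixed_anova(long, "ratio", "condition", "group", "participant_id")
cat("\nCondition x group ANOVA on generation ratios:\n")
print(an)

jsonlite::write_json(
  list(chance_tests = tests, anova = an),
  "results/pdp_results.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)
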