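#!/usr/bin/env Rscript
# Stage 3 — unit-of-five-blocks learning scores.
#
# For each participant and unit (blocks 1-5, ..., 21-25): statistical
# learning score (pooled median RT of low- minus high-probability
# triplet trials), the standardized score (divided by the unit mean RT)
# and the general-skill median RT. Group trajectories are compared with
# mixed-design ANOVAs (unit x group).

suppressPackageStartupMessages(library(asrtlearn))

flagged <- readr::read_csv("results/data/trials_flagged.csv",
                           show_col_types = FALSE, progress = FALSE)
units <- score_cohort(flagged)
readr::write_csv(units, "results/units.csv")

complete <- units |>
  dplyr::group_by(participant_id) |>
  dplyr::filter(!any(is.na(learning_score)) &
                  !any(is.na(general_skill_rt))) |>
  dplyr::ungroup()

sl <- mixed_anova(complete, "learning_score", "unit", "group",
                  "participant_id")
gs <- mixed_anova(complete, "general_skill_rt", "unit", "group",
                  "participant_id")

cat("Statistical learning (unit x group):\n"); print(sl)
cat("\nGeneral skill RT (unit x group):\n"); print(gs)

overall <- stats::aggregate(learning_score ~ participant_id + group,
                            complete, mean)
cat("\nOverall statistical learning by group:\n")
print(group_descriptives(overall$learning_score, overall$group))

jsonlite::write_json(
  list(statistical_learning = sl, general_skill = gs,
       descriptives = group_descriptives(overall$learning_score,
                                         overall$group)),
  "results/unit_anovas.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)
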