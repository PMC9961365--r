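#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Three groups differing only in the between-block rest period: fixed
# 15 s, fixed 30 s, or self-paced (lognormal rests with median 10.58 s
# and mean 16.67 s). 90 participants per group, 25 learning blocks of 80
# trials each, every participant randomly assigned one of the 24 ASRT
# sequences.

suppressPackageStartupMessages(library(asrtlearn))

seed <- 20230223L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(seed = seed, sim = sim_config(seed = seed))
write_run_config(cfg, "results/data/config.json")

cat("Simulating", cfg$sim$n_per_group, "participants per group ...\n")
trials <- simulate_cohort(cfg$sim)
write_trials(trials, "results/data/trials.csv")
parts <- participants_table(trials)
readr::write_csv(parts, "results/data/participants.csv")

cat(sprintf("-> %d participants, %d trials (%s)\n",
            nrow(parts), nrow(trials), "results/data/trials.csv"))
rests <- trials$rest_before_s[trials$trial == 1L & trials$block > 1L &
                                trials$group == "self_paced"]
cat(sprintf("self-paced rests: mean %.2f s, median %.2f s\n",
            mean(rests), median(rests)))
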