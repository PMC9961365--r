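# Shared fixtures and independent oracles for the test suite.

# Independent triplet oracle: determines high/low for the position triple
# (a, b, c) straight from the pattern ordering, without touching the
# package's successor map. In the cyclic pattern, the pattern element
# following `a` is the one after `a`'s slot.
oracle_is_high <- function(a, b, c, pattern) {
  idx <- match(a, pattern)
  expected <- pattern[(idx %% 4) + 1]
  c == expected
}

# Does a flagged trial carry the given exclusion reason?
has_flag <- function(trials, reason) {
  grepl(reason, trials$exclusion_reasons, fixed = TRUE)
}

# Brute-force sort-based median (independent of stats::median).
sort_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Noiseless simulator settings: deterministic RT plant with a constant
# high/low gap `delta` (growth rate Inf saturates delta immediately).
noiseless_config <- function(delta = 20, ramp = 0, fatigue = 0,
                             skill = 0, n_per_group = 1L, seed = 11L,
                             n_blocks = 25L) {
  sim_config(
    n_per_group = n_per_group, n_blocks = n_blocks,
    baseline_rt = 450, skill_gain = skill, skill_growth_rate = 0.2,
    learning_effect_max = delta, learning_growth_rate = Inf,
    learning_online_ramp = ramp, fatigue_slope = fatigue,
    offline_recovery = 4 * fatigue,
    noise_sd = 0, error_rate = 0, long_rt_rate = 0, seed = seed
  )
}

# Classify + flag one simulated participant.
prepare_participant <- function(trials) {
  flag_trials(classify_triplets(trials))
}

# Cache expensive simulations across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A mid-sized noisy single-group cohort reused by several suites:
# 50 participants x 25 blocks x 80 trials = 100,000 trials.
noisy_cohort_flagged <- function() {
  cached("noisy50", {
    cfg <- sim_config(n_per_group = 50L, groups = "fixed_15", seed = 202L)
    prepare_participant(simulate_cohort(cfg))
  })
}

# Hand-built 5-block fixture (50 trials) under pattern 1-2-3-4 with known
# flags in block 1: trials 3 and 5 are trills, 7 a repetition, 4
# incorrect, 6 has a 1200 ms RT; blocks 2-5 are clean (positions cycle
# 1,2,3,4,...). Exactly 5 analysis-flagged trials out of 50.
toy_block_fixture <- function() {
  block1 <- tibble::tibble(
    block = 1L, trial = 1:10,
    position = c(1L, 2L, 1L, 3L, 1L, 1L, 1L, 2L, 3L, 4L),
    correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    rt_ms = c(500, 500, 500, 500, 500, 1200, 500, 500, 500, 500)
  )
  clean <- lapply(2:5, function(b) {
    tibble::tibble(
      block = b, trial = 1:10,
      position = rep(1:4, length.out = 10),
      correct = TRUE, rt_ms = 500
    )
  })
  fixture <- dplyr::bind_rows(c(list(block1), clean))
  fixture$participant_id <- "toy"
  fixture$response <- fixture$position
  fixture
}
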