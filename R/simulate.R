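#' Simulation configuration for a synthetic ASRT cohort
#'
#' The generative model mirrors the structure the analysis assumes. Per
#' trial,
#' `RT = baseline_rt - skill(block) + fatigue(block, bin) - delta(block, bin) * [high] + noise`,
#' floored at 150 ms, where
#' * `skill(b) = skill_gain * (1 - exp(-skill_growth_rate * (b - 1)))` is
#'   the saturating general speedup across blocks,
#' * `delta(b, bin) = learning_effect_max * (1 - exp(-learning_growth_rate * b))
#'   + learning_online_ramp * (bin - 1) / 4` is the high/low-probability RT
#'   gap: a saturating across-block growth plus a linear within-block ramp
#'   (the gain made online within a block, mostly reset by the next rest),
#' * `fatigue(b, bin) = carry(b) + fatigue_slope * (bin - 1)` is the
#'   within-block slowing; across each rest the accumulated fatigue is
#'   reduced by `offline_recovery` ms (the default fully resets it, giving
#'   the speedup after every rest).
#' With probability `long_rt_rate` an RT is replaced by a uniform draw in
#' (1000, 1500] ms; responses are correct with probability
#' `1 - error_rate`. Rest durations are fixed (15 or 30 s) for the fixed
#' groups and lognormal for the self-paced group, parameterised so the
#' median is 10.58 s and the mean 16.67 s.
#'
#' @param n_per_group Participants per group (default 90, the study-scale
#'   cohort).
#' @param groups Character subset of
#'   `c("self_paced", "fixed_15", "fixed_30")`.
#' @param n_blocks,trials_per_block Task dimensions (defaults 25 and 80).
#' @param baseline_rt,skill_gain,skill_growth_rate,learning_effect_max,learning_growth_rate,learning_online_ramp,fatigue_slope,offline_recovery,noise_sd
#'   RT-model parameters in ms (rates per block / per bin as described
#'   above).
#' @param error_rate,long_rt_rate Injection probabilities.
#' @param selfpaced_rest_log_mu,selfpaced_rest_log_sigma Lognormal
#'   parameters (log-seconds) of the self-paced rest durations.
#' @param age_mean,age_sd Cohort age distribution (years).
#' @param block_start_latency_mean,block_start_latency_sd Normal
#'   block-start latency parameters (ms).
#' @param seed Integer cohort seed; every participant's sub-stream is
#'   derived deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 90L,
                       groups = c("self_paced", "fixed_15", "fixed_30"),
                       n_blocks = 25L,
                       trials_per_block = 80L,
                       baseline_rt = 450,
                       skill_gain = 80,
                       skill_growth_rate = 0.12,
                       learning_effect_max = 25,
                       learning_growth_rate = 0.15,
                       learning_online_ramp = 4,
                       fatigue_slope = 5,
                       offline_recovery = 20,
                       noise_sd = 60,
                       error_rate = 0.09,
                       long_rt_rate = 0.0024,
                       selfpaced_rest_log_mu = log(10.58),
                       selfpaced_rest_log_sigma = 0.954,
                       age_mean = 21.5,
                       age_sd = 2.2,
                       block_start_latency_mean = 500,
                       block_start_latency_sd = 150,
                       seed = 1L) {
  groups <- match.arg(groups, several.ok = TRUE)
  cfg <- list(
    n_per_group = as.integer(n_per_group), groups = groups,
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    baseline_rt = baseline_rt, skill_gain = skill_gain,
    skill_growth_rate = skill_growth_rate,
    learning_effect_max = learning_effect_max,
    learning_growth_rate = learning_growth_rate,
    learning_online_ramp = learning_online_ramp,
    fatigue_slope = fatigue_slope, offline_recovery = offline_recovery,
    noise_sd = noise_sd, error_rate = error_rate,
    long_rt_rate = long_rt_rate,
    selfpaced_rest_log_mu = selfpaced_rest_log_mu,
    selfpaced_rest_log_sigma = selfpaced_rest_log_sigma,
    age_mean = age_mean, age_sd = age_sd,
    block_start_latency_mean = block_start_latency_mean,
    block_start_latency_sd = block_start_latency_sd,
    seed = as.integer(seed)
  )
  for (p in c("error_rate", "long_rt_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("`%s` must be in [0, 1]", p), call. = FALSE)
    }
  }
  for (p in c("baseline_rt", "skill_gain", "learning_effect_max",
              "fatigue_slope", "offline_recovery", "noise_sd")) {
    if (cfg[[p]] < 0) stop(sprintf("`%s` must be >= 0", p), call. = FALSE)
  }
  if (cfg$n_blocks < 2L) stop("`n_blocks` must be >= 2", call. = FALSE)
  if (cfg$n_per_group < 1L) stop("`n_per_group` must be >= 1", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# High/low RT gap at (block, bin); bins are 1..5 within a block.
delta_at <- function(cfg, block, bin) {
  base <- cfg$learning_effect_max *
    (1 - exp(-cfg$learning_growth_rate * block))
  base + cfg$learning_online_ramp * (bin - 1) / 4
}

# General-skill speedup at a block (ms subtracted from baseline).
skill_at <- function(cfg, block) {
  cfg$skill_gain * (1 - exp(-cfg$skill_growth_rate * (block - 1)))
}

#' Simulate one ASRT participant
#'
#' Generates the participant's stimulus stream under a randomly assigned
#' (or supplied) sequence and draws responses from the RT model described
#' in [sim_config()]. Deterministic given `(config$seed, participant_id)`.
#'
#' @param config A [sim_config()].
#' @param group `"self_paced"`, `"fixed_15"` or `"fixed_30"`.
#' @param participant_id Identifier string.
#' @param spec Optional [asrt_sequence()]; default random over the 24.
#' @param late_starter If `TRUE`, block-start latencies exceed 1500 ms in
#'   six blocks (exercises the quality-control rule).
#' @return A tibble in the tidy trial schema: `participant_id`, `group`,
#'   `age`, `sequence`, `block`, `trial`, `position`, `response`, `rt_ms`,
#'   `correct`, `rest_before_s`, `block_start_latency_ms`.
#' @export
simulate_participant <- function(config, group, participant_id,
                                 spec = NULL, late_starter = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% c("self_paced", "fixed_15", "fixed_30")) {
    stop("unknown group: ", group, call. = FALSE)
  }
  pseed <- derive_seed(config$seed, participant_id)
  with_seed(pseed, {
    if (is.null(spec)) spec <- enumerate_sequences()[[sample.int(24L, 1L)]]
    stream <- generate_stream(spec, config$n_blocks, config$trials_per_block,
                              seed = sample.int(.Machine$integer.max, 1L))
    n <- nrow(stream)
    cl <- classify_triplets(stream, spec)
    bin <- ceiling(stream$trial * 5 / config$trials_per_block)

    # accumulated fatigue carried into each block after partial recovery
    per_block_rise <- config$fatigue_slope * 4
    carry <- numeric(config$n_blocks)
    for (b in seq_len(config$n_blocks)[-1]) {
      carry[b] <- max(0, carry[b - 1] + per_block_rise - config$offline_recovery)
    }

    rt <- config$baseline_rt -
      skill_at(config, stream$block) +
      carry[stream$block] + config$fatigue_slope * (bin - 1) -
      delta_at(config, stream$block, bin) * (cl$triplet == "high") +
      rnorm(n, 0, config$noise_sd)
    rt <- pmax(rt, 150)
    long <- runif(n) < config$long_rt_rate
    rt[long] <- runif(sum(long), 1000, 1500)
    # uniform draw in (1000, 1500]: exclude the open lower endpoint
    rt[long & rt <= 1000] <- 1500

    correct <- rbinom(n, 1L, 1 - config$error_rate) == 1L
    response <- stream$position
    wrong <- which(!correct)
    if (length(wrong)) {
      response[wrong] <- vapply(
        stream$position[wrong],
        function(p) sample(setdiff(1:4, p), 1L),
        integer(1)
      )
    }

    rests <- switch(group,
      fixed_15 = rep(15, config$n_blocks - 1L),
      fixed_30 = rep(30, config$n_blocks - 1L),
      self_paced = rlnorm(config$n_blocks - 1L,
                          config$selfpaced_rest_log_mu,
                          config$selfpaced_rest_log_sigma)
    )
    latency <- rnorm(config$n_blocks, config$block_start_latency_mean,
                     config$block_start_latency_sd)
    latency <- pmax(latency, 50)
    if (late_starter) {
      late_blocks <- sample.int(config$n_blocks, 6L)
      latency[late_blocks] <- runif(6L, 1600, 3000)
    }
    age <- max(18, rnorm(1, config$age_mean, config$age_sd))

    tibble::tibble(
      participant_id = as.character(participant_id),
      group = group,
      age = round(age, 1),
      sequence = format(spec),
      block = stream$block,
      trial = stream$trial,
      position = stream$position,
      response = response,
      rt_ms = round(rt, 1),
      correct = correct,
      rest_before_s = c(NA, rests)[stream$block],
      block_start_latency_ms = round(latency[stream$block], 1)
    )
  })
}

#' Simulate a full cohort
#'
#' @param config A [sim_config()].
#' @return A tibble of all participants' trials (tidy trial schema),
#'   `n_per_group` participants per requested group, each driven by an
#'   independent reproducible sub-stream.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  recs <- list()
  for (g in config$groups) {
    for (i in seq_len(config$n_per_group)) {
      id <- sprintf("%s_%03d", g, i)
      recs[[id]] <- simulate_participant(config, g, id)
    }
  }
  dplyr::bind_rows(recs)
}

#' Participant metadata table of a trial table
#'
#' @param trials A tidy trial table.
#' @return One row per participant: `participant_id`, `group`, `age`,
#'   `sequence`.
#' @export
participants_table <- function(trials) {
  dplyr::distinct(
    trials,
    .data$participant_id, .data$group, .data$age, .data$sequence
  )
}

#' Simulate generation-task (PDP) runs
#'
#' Each run is up to 24 key presses (three rounds of the eight-element
#' alternating sequence). The first two presses are uniform over the four
#' keys; every later press follows the learned pattern transition from the
#' press two back with probability `bias`, and is uniform otherwise.
#' `bias = 0` is pure chance pressing (25% high-probability triplets in
#' the long run); `bias = 1` makes every classifiable press the third
#' element of a high-probability triplet.
#'
#' @param spec An [asrt_sequence()].
#' @param condition `"inclusion"` or `"exclusion"` (metadata only; the
#'   generative model is the bias parameter).
#' @param n_runs Number of runs (the task used 4 per condition).
#' @param bias Probability in `[0, 1]` of following the pattern successor.
#' @param seed Integer seed.
#' @param participant_id Identifier attached to the runs.
#' @return A tibble with columns `participant_id`, `condition`,
#'   `run_index`, `press_index`, `key`.
#' @export
simulate_pdp_runs <- function(spec, condition = c("inclusion", "exclusion"),
                              n_runs = 4L, bias = 0, seed = 1L,
                              participant_id = "sim") {
  stopifnot(inherits(spec, "asrt_sequence"))
  condition <- match.arg(condition)
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("`n_runs` must be >= 1", call. = FALSE)
  if (bias < 0 || bias > 1) stop("`bias` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      key <- integer(24L)
      for (i in 1:24) {
        key[i] <- if (i > 2L && runif(1) < bias) {
          spec$successor[key[i - 2L]]
        } else {
          sample.int(4L, 1L)
        }
      }
      tibble::tibble(
        participant_id = participant_id,
        condition = condition,
        run_index = r,
        press_index = 1:24,
        key = key
      )
    })
    dplyr::bind_rows(runs)
  })
}

#' Simulate PDP runs for a whole cohort
#'
#' @param participants A participant metadata table (see
#'   [participants_table()]).
#' @param bias_inclusion,bias_exclusion Pattern-following bias per
#'   condition; the defaults place mean generation ratios a few points
#'   above the 25% chance level, as observed in inclusion/exclusion data.
#' @param n_runs Runs per condition (default 4).
#' @param seed Integer cohort seed.
#' @return A tibble of presses across participants and both conditions.
#' @export
simulate_pdp_cohort <- function(participants, bias_inclusion = 0.08,
                                bias_exclusion = 0.05, n_runs = 4L,
                                seed = 1L) {
  out <- list()
  for (i in seq_len(nrow(participants))) {
    id <- participants$participant_id[i]
    spec <- asrt_sequence(participants$sequence[i])
    for (cond in c("inclusion", "exclusion")) {
      bias <- if (cond == "inclusion") bias_inclusion else bias_exclusion
      out[[paste(id, cond)]] <- simulate_pdp_runs(
        spec, cond, n_runs = n_runs, bias = bias,
        seed = derive_seed(seed, paste0(id, "/", cond)),
        participant_id = id
      )
    }
  }
  dplyr::bind_rows(out)
}
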