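#' Partition blocks into units of consecutive blocks
#'
#' The 25 learning blocks are analysed in units of five consecutive blocks
#' (blocks 1-5, 6-10, 11-15, 16-20, 21-25) to filter out noise.
#'
#' @param n_blocks Total number of blocks.
#' @param unit_size Blocks per unit (default 5); must divide `n_blocks`.
#' @return A tibble with columns `unit`, `first_block`, `last_block`;
#'   ranges are contiguous, disjoint and cover `1:n_blocks`.
#' @export
unit_partition <- function(n_blocks, unit_size = 5L) {
  n_blocks <- as.integer(n_blocks)
  unit_size <- as.integer(unit_size)
  if (n_blocks < 1L || unit_size < 1L || n_blocks %% unit_size != 0L) {
    stop("`n_blocks` must be a positive multiple of `unit_size`",
         call. = FALSE)
  }
  k <- n_blocks %/% unit_size
  tibble::tibble(
    unit = seq_len(k),
    first_block = (seq_len(k) - 1L) * unit_size + 1L,
    last_block = seq_len(k) * unit_size
  )
}

# median of x restricted to `take`; NA (never 0) when the subset is empty
median_of <- function(x, take) {
  x <- x[take & !is.na(x)]
  if (!length(x)) NA_real_ else stats::median(x)
}

#' Score one unit of trials
#'
#' Statistical learning score = median RT of low-probability triplet
#' trials minus median RT of high-probability triplet trials, medians
#' pooled over all eligible trials of the unit (not averaged per block).
#' The standardized score divides by the unit's mean RT to control for
#' baseline speed. General skill RT is the median over eligible trials
#' regardless of triplet category. Eligible = not excluded by any
#' trial-level rule.
#'
#' @param trials Flagged, classified trials of one participant-unit.
#' @return A one-row tibble: `median_rt_high`, `median_rt_low`,
#'   `learning_score`, `mean_rt`, `standardized_learning`,
#'   `general_skill_rt`, `n_eligible`. Scores are `NA` when a unit has no
#'   eligible high or no eligible low trials.
#' @export
score_unit <- function(trials) {
  if (!all(c("excluded", "triplet", "rt_ms") %in% names(trials))) {
    stop("trials must be classified and flagged before scoring",
         call. = FALSE)
  }
  ok <- !trials$excluded
  rt <- trials$rt_ms
  hi <- median_of(rt, ok & trials$triplet == "high")
  lo <- median_of(rt, ok & trials$triplet == "low")
  mean_rt <- if (any(ok)) mean(rt[ok], na.rm = TRUE) else NA_real_
  learning <- lo - hi
  tibble::tibble(
    median_rt_high = hi,
    median_rt_low = lo,
    learning_score = learning,
    mean_rt = mean_rt,
    standardized_learning = learning / mean_rt,
    general_skill_rt = median_of(rt, ok),
    n_eligible = sum(ok)
  )
}

#' Unit scores for one participant
#'
#' @param trials One participant's classified and flagged learning-block
#'   trials; blocks must run contiguously from 1 and their count must be
#'   divisible by `unit_size`.
#' @param unit_size Blocks per unit (default 5).
#' @param standardize_by Denominator of the standardized learning score:
#'   the same unit's mean RT (`"unit"`, the default) or the
#'   participant's mean eligible RT across all blocks
#'   (`"participant"`).
#' @return A tibble with one row per unit (columns of [score_unit()] plus
#'   `unit`).
#' @export
score_participant <- function(trials, unit_size = 5L,
                              standardize_by = c("unit", "participant")) {
  standardize_by <- match.arg(standardize_by)
  blocks <- sort(unique(trials$block))
  if (!identical(as.integer(blocks), seq_len(length(blocks)))) {
    stop("blocks must be contiguous from 1", call. = FALSE)
  }
  parts <- unit_partition(length(blocks), unit_size)
  out <- lapply(seq_len(nrow(parts)), function(i) {
    u <- trials[trials$block >= parts$first_block[i] &
                  trials$block <= parts$last_block[i], , drop = FALSE]
    cbind(tibble::tibble(unit = parts$unit[i]), score_unit(u))
  })
  out <- tibble::as_tibble(do.call(rbind, out))
  if (standardize_by == "participant") {
    ok <- !trials$excluded & !is.na(trials$rt_ms)
    out$standardized_learning <- out$learning_score / mean(trials$rt_ms[ok])
  }
  out
}

#' Unit scores for a cohort
#'
#' @param trials Classified and flagged cohort trial table.
#' @param unit_size Blocks per unit (default 5).
#' @param standardize_by Denominator of the standardized learning score:
#'   per-unit mean RT (`"unit"`, default), per-participant mean RT
#'   (`"participant"`), or the grand mean eligible RT of the whole
#'   cohort (`"grand"`).
#' @return A tidy tibble: `participant_id`, `group`, `unit`, and the
#'   [score_unit()] columns.
#' @export
score_cohort <- function(trials, unit_size = 5L,
                         standardize_by = c("unit", "participant",
                                            "grand")) {
  standardize_by <- match.arg(standardize_by)
  per_part <- if (standardize_by == "grand") "unit" else standardize_by
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    tt <- trials[trials$participant_id == id, , drop = FALSE]
    scores <- score_participant(tt, unit_size, standardize_by = per_part)
    cbind(
      tibble::tibble(
        participant_id = id,
        group = if ("group" %in% names(tt)) tt$group[1L] else NA_character_
      ),
      scores
    )
  })
  out <- tibble::as_tibble(do.call(rbind, out))
  if (standardize_by == "grand") {
    ok <- !trials$excluded & !is.na(trials$rt_ms)
    out$standardized_learning <- out$learning_score / mean(trials$rt_ms[ok])
  }
  out
}
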