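#' Partition a block into bins of consecutive trials
#'
#' Each 80-trial block is divided into five bins of 16 consecutive trial
#' positions. Bins are defined on the raw design grid: excluded trials
#' reduce the eligible count inside a bin, they never shift bin
#' boundaries.
#'
#' @param n_trials Trials per block (default 80).
#' @param n_bins Number of bins (default 5); must divide `n_trials`.
#' @return A tibble `bin`, `first_trial`, `last_trial`.
#' @export
bin_partition <- function(n_trials = 80L, n_bins = 5L) {
  n_trials <- as.integer(n_trials)
  n_bins <- as.integer(n_bins)
  if (n_trials < 1L || n_bins < 1L || n_trials %% n_bins != 0L) {
    stop("`n_trials` must be a positive multiple of `n_bins`",
         call. = FALSE)
  }
  w <- n_trials %/% n_bins
  tibble::tibble(
    bin = seq_len(n_bins),
    first_trial = (seq_len(n_bins) - 1L) * w + 1L,
    last_trial = seq_len(n_bins) * w
  )
}

#' Per-bin learning scores and median RTs
#'
#' For every participant, block and bin, computes the bin statistical
#' learning score (median RT of eligible low-probability trials minus
#' median of eligible high-probability trials) and the bin median RT over
#' all eligible trials (the general-skill measure). A bin with no
#' eligible high or no eligible low trials gets an `NA` learning score.
#'
#' @param trials Classified and flagged cohort trial table; every block
#'   must contain exactly `n_trials` trial positions.
#' @param n_trials,n_bins Bin grid (defaults 80 and 5).
#' @return A tibble `participant_id`, `group`, `block`, `bin`,
#'   `learning_score`, `median_rt`.
#' @export
bin_scores <- function(trials, n_trials = 80L, n_bins = 5L) {
  bin_partition(n_trials, n_bins) # validates the grid
  if (!all(c("excluded", "triplet", "rt_ms") %in% names(trials))) {
    stop("trials must be classified and flagged before binning",
         call. = FALSE)
  }
  bad <- dplyr::count(trials, .data$participant_id, .data$block)
  if (any(bad$n != n_trials)) {
    stop("every block must have exactly ", n_trials, " trials",
         call. = FALSE)
  }
  trials$bin <- ceiling(trials$trial * n_bins / n_trials)
  grp <- dplyr::group_by(trials, .data$participant_id, .data$block,
                         .data$bin)
  out <- dplyr::summarise(
    grp,
    group = if ("group" %in% names(trials)) .data$group[1L] else NA_character_,
    learning_score =
      median_of(.data$rt_ms, !.data$excluded & .data$triplet == "low") -
      median_of(.data$rt_ms, !.data$excluded & .data$triplet == "high"),
    median_rt = median_of(.data$rt_ms, !.data$excluded),
    n_raw = dplyr::n(),
    n_eligible = sum(!.data$excluded),
    .groups = "drop"
  )
  out[, c("participant_id", "group", "block", "bin", "learning_score",
          "median_rt", "n_raw", "n_eligible")]
}

# last-bin minus first-bin within each block of one participant
online_from_bins <- function(bins, col) {
  n_bins <- max(bins$bin)
  first <- bins[bins$bin == 1L, ]
  last <- bins[bins$bin == n_bins, ]
  stopifnot(identical(first$block, last$block))
  tibble::tibble(block = first$block,
                 value = last[[col]] - first[[col]])
}

# next block's first bin minus this block's last bin
offline_from_bins <- function(bins, col) {
  n_bins <- max(bins$bin)
  first <- bins[bins$bin == 1L, ]
  last <- bins[bins$bin == n_bins, ]
  nb <- nrow(first)
  if (nb < 2L) stop("offline changes need at least 2 blocks", call. = FALSE)
  tibble::tibble(
    rest = seq_len(nb - 1L),
    value = first[[col]][-1L] - last[[col]][-nb]
  )
}

#' Online and offline change scores
#'
#' Online change of a block = last-bin score minus first-bin score (the
#' change from the beginning to the end of the block); offline change of
#' a rest = next block's first-bin score minus the previous block's
#' last-bin score. Both are computed for the statistical learning score
#' (`measure = "sl"`) and for the bin median RT / general skill
#' (`measure = "gs"`). A 25-block participant yields 25 online and 24
#' offline scores per measure. Sign conventions: positive online `sl` is
#' within-block gain; negative offline `sl` is forgetting over the rest;
#' positive online `gs` is within-block slowing; negative offline `gs` is
#' the RT drop across the rest.
#'
#' @param bins A bin-score table from [bin_scores()].
#' @return A long tibble `participant_id`, `group`, `measure` (sl/gs),
#'   `phase` (online/offline), `index` (block for online, rest for
#'   offline), `value` (ms; `NA` where a touched bin score was
#'   undefined).
#' @export
change_scores <- function(bins) {
  ids <- unique(bins$participant_id)
  rows <- list()
  for (id in ids) {
    b <- bins[bins$participant_id == id, , drop = FALSE]
    b <- b[order(b$block, b$bin), ]
    g <- b$group[1L]
    for (m in c("sl", "gs")) {
      col <- if (m == "sl") "learning_score" else "median_rt"
      on <- online_from_bins(b, col)
      off <- offline_from_bins(b, col)
      rows[[paste(id, m)]] <- dplyr::bind_rows(
        tibble::tibble(participant_id = id, group = g, measure = m,
                       phase = "online", index = on$block,
                       value = on$value),
        tibble::tibble(participant_id = id, group = g, measure = m,
                       phase = "offline", index = off$rest,
                       value = off$value)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-participant mean change scores
#'
#' Averages each participant's online scores (over blocks) and offline
#' scores (over rests), separately for statistical learning and general
#' skill, ignoring missing entries.
#'
#' @param changes Long change-score table from [change_scores()].
#' @return A tibble `participant_id`, `group`, `mean_online_sl`,
#'   `mean_offline_sl`, `mean_online_gs`, `mean_offline_gs`.
#' @export
mean_change_scores <- function(changes) {
  grp <- dplyr::group_by(changes, .data$participant_id, .data$group,
                         .data$measure, .data$phase)
  m <- dplyr::summarise(grp, mean = mean(.data$value, na.rm = TRUE),
                        .groups = "drop")
  wide <- tidyr::pivot_wider(
    m,
    names_from = c("phase", "measure"), values_from = "mean",
    names_glue = "mean_{phase}_{measure}"
  )
  wide[, c("participant_id", "group", "mean_online_sl", "mean_offline_sl",
           "mean_online_gs", "mean_offline_gs")]
}

#' Group-level summary of change scores
#'
#' Per group and measure/phase: n, mean, SD of the participant mean
#' change scores, plus a one-sample t test against zero (is there online
#' learning / offline forgetting at the group level?).
#'
#' @param changes Long change-score table from [change_scores()].
#' @return A tibble with one row per (group, measure, phase) and columns
#'   `n`, `mean`, `sd`, `t`, `df`, `p`.
#' @export
summarize_changes <- function(changes) {
  pm <- mean_change_scores(changes)
  long <- tidyr::pivot_longer(
    pm, dplyr::starts_with("mean_"),
    names_to = c("phase", "measure"), names_pattern = "mean_(.*)_(.*)",
    values_to = "value"
  )
  grp <- dplyr::group_by(long, .data$group, .data$measure, .data$phase)
  dplyr::summarise(
    grp,
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    t = one_sample_t(.data$value[!is.na(.data$value)], 0)$t,
    df = one_sample_t(.data$value[!is.na(.data$value)], 0)$df,
    p = one_sample_t(.data$value[!is.na(.data$value)], 0)$p,
    .groups = "drop"
  )
}
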