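#' Filter generation-task runs by trill/repetition content
#'
#' In the process dissociation procedure (PDP), runs in which more than
#' 50% of the classifiable key presses (the 3rd press onward within a
#' run) are trills (x-y-x) or repetitions (x-x-x) are removed, since such
#' pressing carries no information about sequence knowledge. Exactly 50%
#' is kept (the rule is strict). Filtering never alters press content.
#'
#' @param runs A press table: `participant_id`, `condition`, `run_index`,
#'   `press_index`, `key` (1-4).
#' @return A tibble with one row per run: `participant_id`, `condition`,
#'   `run_index`, `n_presses`, `trill_rep_frac`, `kept`.
#' @export
filter_pdp_runs <- function(runs) {
  if (anyNA(runs$key) || !all(runs$key %in% 1:4)) {
    stop("malformed data: `key` must be in 1..4", call. = FALSE)
  }
  grp <- dplyr::group_by(runs, .data$participant_id, .data$condition,
                         .data$run_index)
  out <- dplyr::summarise(
    grp,
    n_presses = dplyr::n(),
    trill_rep_frac = {
      k <- .data$key[order(.data$press_index)]
      n <- length(k)
      if (n < 3L) {
        NA_real_
      } else {
        i <- 3:n
        trill <- k[i - 2L] == k[i] & k[i - 1L] != k[i]
        reps <- k[i - 2L] == k[i - 1L] & k[i - 1L] == k[i]
        mean(trill | reps)
      }
    },
    .groups = "drop"
  )
  out$kept <- !is.na(out$trill_rep_frac) & out$trill_rep_frac <= 0.5
  out$kept[is.na(out$trill_rep_frac)] <- FALSE # runs too short to classify
  out
}

#' High-probability triplet ratio of kept generation runs
#'
#' The proportion (as a percentage) of classifiable presses — the 3rd
#' press onward within each run, runs never concatenated — that close a
#' high-probability triplet under the participant's sequence. Trill and
#' repetition presses stay in the denominator, which keeps the chance
#' level at exactly 25%.
#'
#' @param runs Press table of the kept runs of one participant-condition.
#' @param spec The participant's [asrt_sequence()].
#' @return Percentage in `[0, 100]`; error if `runs` is empty.
#' @export
high_prob_ratio <- function(runs, spec) {
  stopifnot(inherits(spec, "asrt_sequence"))
  if (nrow(runs) == 0L) {
    stop("no kept runs: ratio undefined", call. = FALSE)
  }
  if (anyNA(runs$key) || !all(runs$key %in% 1:4)) {
    stop("malformed data: `key` must be in 1..4", call. = FALSE)
  }
  high <- 0L
  total <- 0L
  for (rows in split(seq_len(nrow(runs)),
                     paste(runs$participant_id, runs$condition,
                           runs$run_index))) {
    k <- runs$key[rows][order(runs$press_index[rows])]
    n <- length(k)
    if (n < 3L) next
    i <- 3:n
    high <- high + sum(k[i] == spec$successor[k[i - 2L]])
    total <- total + length(i)
  }
  if (total == 0L) stop("no classifiable presses", call. = FALSE)
  100 * high / total
}

#' Per-participant PDP ratios for a cohort
#'
#' Applies the trill/repetition run filter, then pools each participant's
#' kept runs within a condition into a single high-probability triplet
#' percentage. Participants whose runs are all removed in a condition get
#' an `NA` ratio there (fully removed).
#'
#' @param runs Cohort press table.
#' @param participants Participant metadata with `participant_id` and
#'   `sequence` (and optionally `group`).
#' @return A tibble `participant_id`, `group`, `condition`, `n_kept_runs`,
#'   `ratio`.
#' @export
pdp_ratios <- function(runs, participants) {
  flt <- filter_pdp_runs(runs)
  keep_key <- paste(flt$participant_id, flt$condition, flt$run_index)
  kept_keys <- keep_key[flt$kept]
  out <- list()
  for (i in seq_len(nrow(participants))) {
    id <- participants$participant_id[i]
    spec <- asrt_sequence(participants$sequence[i])
    g <- participants$group[i] %||% NA_character_
    for (cond in unique(runs$condition[runs$participant_id == id])) {
      sub <- runs[runs$participant_id == id & runs$condition == cond, ]
      sub <- sub[paste(sub$participant_id, sub$condition, sub$run_index)
                 %in% kept_keys, ]
      n_kept <- length(unique(sub$run_index))
      ratio <- if (n_kept == 0L) NA_real_ else high_prob_ratio(sub, spec)
      out[[paste(id, cond)]] <- tibble::tibble(
        participant_id = id, group = g, condition = cond,
        n_kept_runs = n_kept, ratio = ratio
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Compare generation ratios to the chance level
#'
#' One-sample t test of per-participant high-probability triplet
#' percentages against chance (25%: after any two presses, one of the
#' four keys closes a high-probability triplet). Ratios above chance in
#' the exclusion condition indicate knowledge that is applied even when
#' participants try to avoid it, i.e. implicit knowledge.
#'
#' @param ratios Numeric vector of per-participant percentages (`NA`s
#'   dropped).
#' @param chance Chance level in percent (default 25).
#' @return A `ttest_result` (see [one_sample_t()]).
#' @export
chance_test <- function(ratios, chance = 25) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2L) {
    stop("need at least 2 participants for the chance-level test",
         call. = FALSE)
  }
  one_sample_t(ratios, chance)
}
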