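#' Quality-control criteria
#'
#' Thresholds for trial- and participant-level exclusion. Defaults follow
#' the standard ASRT quality-control rules: trials with RT above 1000 ms
#' are dropped; participants are dropped when overall task accuracy is
#' below 80%, when the block-start latency exceeds 1500 ms in at least
#' five blocks, when the mean RT of block-initial trials exceeds 1000 ms,
#' or when age exceeds 35 years.
#'
#' @param accuracy_min Minimum proportion correct (default 0.80).
#' @param rt_max_ms Trial-level RT cutoff, strict (default 1000).
#' @param latency_limit_ms Block-start latency limit (default 1500).
#' @param latency_block_min Number of late blocks that triggers exclusion
#'   (default 5).
#' @param first_trial_rt_max_ms Cutoff for the mean RT of block-initial
#'   trials (default 1000).
#' @param age_max Maximum age in years (default 35).
#' @return A list of class `qc_criteria`.
#' @export
qc_criteria <- function(accuracy_min = 0.80, rt_max_ms = 1000,
                        latency_limit_ms = 1500, latency_block_min = 5L,
                        first_trial_rt_max_ms = 1000, age_max = 35) {
  stopifnot(accuracy_min > 0, rt_max_ms > 0, latency_limit_ms > 0,
            latency_block_min > 0, first_trial_rt_max_ms > 0, age_max > 0)
  structure(
    list(accuracy_min = accuracy_min, rt_max_ms = rt_max_ms,
         latency_limit_ms = latency_limit_ms,
         latency_block_min = as.integer(latency_block_min),
         first_trial_rt_max_ms = first_trial_rt_max_ms, age_max = age_max),
    class = "qc_criteria"
  )
}

#' Flag trials for exclusion
#'
#' Annotates each trial with its exclusion reasons: `incorrect` (wrong or
#' missing response), `trill` (x-y-x triplet), `repetition` (x-x-x),
#' `long_rt` (RT strictly above the cutoff) and `unclassifiable` (the
#' first two trials of each block). Reasons are computed independently
#' from the raw trial, so a trial can carry several reasons and flagging
#' is idempotent and order-independent. No RT or position is modified.
#'
#' @param trials A trial table already passed through
#'   [classify_triplets()].
#' @param criteria A [qc_criteria()]; only `rt_max_ms` is used here.
#' @return `trials` with added columns `excluded` (logical) and
#'   `exclusion_reasons` (comma-separated string, `""` when kept).
#' @export
flag_trials <- function(trials, criteria = qc_criteria()) {
  need <- c("triplet", "is_trill", "is_repetition", "correct", "rt_ms")
  if (!all(need %in% names(trials))) {
    stop("trials must be classified before flagging; missing: ",
         paste(setdiff(need, names(trials)), collapse = ", "),
         call. = FALSE)
  }
  has_response <- if ("response" %in% names(trials)) {
    !is.na(trials$response)
  } else {
    rep(TRUE, nrow(trials))
  }
  reasons <- list(
    incorrect = !trials$correct | !has_response,
    trill = trials$is_trill,
    repetition = trials$is_repetition,
    long_rt = !is.na(trials$rt_ms) & trials$rt_ms > criteria$rt_max_ms,
    unclassifiable = trials$triplet == "unclassifiable"
  )
  mat <- do.call(cbind, reasons)
  trials$excluded <- rowSums(mat) > 0
  trials$exclusion_reasons <- apply(mat, 1L, function(r) {
    paste(names(reasons)[r], collapse = ",")
  })
  trials
}

# reasons counted in the overlap-aware "total excluded" (the analysis
# exclusions; unclassifiable warm-up trials are reported separately)
ANALYSIS_REASONS <- c("incorrect", "trill", "repetition", "long_rt")

has_reason <- function(trials, reason) {
  grepl(reason, trials$exclusion_reasons, fixed = TRUE)
}

#' Participant-level quality control
#'
#' @param trials One participant's trial table (learning blocks,
#'   `block >= 1`).
#' @param criteria A [qc_criteria()].
#' @return A list with `kept` (logical) and `reasons` (character vector of
#'   triggered rules, empty when kept). Latency-based rules are skipped
#'   with a warning when `block_start_latency_ms` is absent or all-`NA`.
#' @export
participant_filter <- function(trials, criteria = qc_criteria()) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  learning <- trials[trials$block >= 1L, , drop = FALSE]
  reasons <- character()

  accuracy <- mean(learning$correct, na.rm = TRUE)
  if (accuracy < criteria$accuracy_min) reasons <- c(reasons, "accuracy")

  lat <- learning$block_start_latency_ms %||% rep(NA_real_, nrow(learning))
  lat_by_block <- tapply(lat, learning$block, function(x) x[1L])
  if (all(is.na(lat_by_block))) {
    warning("block-start latencies absent; latency rule skipped for ",
            learning$participant_id[1L], call. = FALSE)
  } else if (sum(lat_by_block > criteria$latency_limit_ms, na.rm = TRUE) >=
             criteria$latency_block_min) {
    reasons <- c(reasons, "late_block_start")
  }

  first_rt <- learning$rt_ms[learning$trial == 1L]
  if (length(first_rt) &&
      mean(first_rt, na.rm = TRUE) > criteria$first_trial_rt_max_ms) {
    reasons <- c(reasons, "slow_first_trials")
  }

  age <- learning$age[1L] %||% NA_real_
  if (!is.na(age) && age > criteria$age_max) reasons <- c(reasons, "age")

  list(kept = length(reasons) == 0L, reasons = reasons)
}

#' Apply participant-level quality control to a cohort
#'
#' @param trials A flagged cohort trial table.
#' @param criteria A [qc_criteria()].
#' @return A list: `trials` (rows of kept participants only) and
#'   `participants` (tibble `participant_id`, `kept`, `reasons`).
#' @export
apply_qc <- function(trials, criteria = qc_criteria()) {
  ids <- unique(trials$participant_id)
  status <- lapply(ids, function(id) {
    res <- participant_filter(
      trials[trials$participant_id == id, , drop = FALSE], criteria
    )
    tibble::tibble(
      participant_id = id,
      kept = res$kept,
      reasons = paste(res$reasons, collapse = ",")
    )
  })
  status <- dplyr::bind_rows(status)
  keep_ids <- status$participant_id[status$kept]
  list(
    trials = trials[trials$participant_id %in% keep_ids, , drop = FALSE],
    participants = status
  )
}

#' Build an auditable exclusion report
#'
#' Counts excluded trials per reason (overlaps allowed: a trial may be
#' both incorrect and a trill) and the overlap-aware total across the
#' analysis exclusions (incorrect, trill, repetition, long RT), which is
#' therefore at most — and usually less than — the sum of the per-reason
#' counts. The two warm-up trials of each block, which cannot be
#' categorised as triplet endings, are reported on their own row and do
#' not enter the total.
#'
#' @param trials A flagged cohort trial table.
#' @param participants Optional participant status tibble from
#'   [apply_qc()].
#' @return A list of class `exclusion_report`: `n_trials`, `by_reason`
#'   (tibble reason/n/pct), `total_excluded`, `pct_excluded`,
#'   `participants`.
#' @export
build_exclusion_report <- function(trials, participants = NULL) {
  if (!"exclusion_reasons" %in% names(trials)) {
    stop("trials must be flagged first (see flag_trials)", call. = FALSE)
  }
  n <- nrow(trials)
  all_reasons <- c(ANALYSIS_REASONS, "unclassifiable")
  by_reason <- tibble::tibble(
    reason = all_reasons,
    n = unname(vapply(all_reasons, function(r) sum(has_reason(trials, r)),
                      integer(1))),
    pct = NA_real_
  )
  by_reason$pct <- round(100 * by_reason$n / n, 2)
  any_analysis <- Reduce(`|`, lapply(ANALYSIS_REASONS, has_reason,
                                     trials = trials))
  total <- sum(any_analysis)
  structure(
    list(
      n_trials = n,
      by_reason = by_reason,
      total_excluded = total,
      pct_excluded = round(100 * total / n, 2),
      participants = participants
    ),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report —", x$n_trials, "trials\n")
  for (i in seq_len(nrow(x$by_reason))) {
    cat(sprintf("  %-15s %8d (%5.2f%%)\n", x$by_reason$reason[i],
                x$by_reason$n[i], x$by_reason$pct[i]))
  }
  cat(sprintf("  total excluded  %8d (%5.2f%%), overlap-aware\n",
              x$total_excluded, x$pct_excluded))
  if (!is.null(x$participants)) {
    cat(sprintf("  participants kept: %d of %d\n",
                sum(x$participants$kept), nrow(x$participants)))
  }
  invisible(x)
}
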