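#' Construct an ASRT sequence specification
#'
#' An ASRT sequence is one of the 24 orderings of the four stimulus
#' positions. The four pattern elements cycle (e.g. pattern `2 4 3 1`
#' realises the eight-element stream `2 - r - 4 - r - 3 - r - 1 - r`, `r`
#' random), so the specification induces a successor map on positions: the
#' pattern transition `position -> next pattern position`.
#'
#' @param pattern Integer vector of length 4, a permutation of `1:4`
#'   (positions numbered 1-4 left to right). A string of four digits such
#'   as `"2431"` is also accepted.
#' @return An object of class `asrt_sequence` with elements `pattern`
#'   (integer 4-vector) and `successor` (integer 4-vector: `successor[p]`
#'   is the pattern element that follows position `p`).
#' @examples
#' spec <- asrt_sequence(c(2, 4, 3, 1))
#' spec$successor[2] # 4: in pattern 2-4-3-1, position 2 is followed by 4
#' @export
asrt_sequence <- function(pattern) {
  if (length(pattern) == 1L) {
    # four comma-free digits, as stored in the trial CSV (e.g. "2431")
    pattern <- as.integer(strsplit(as.character(pattern), "")[[1]])
  }
  pattern <- as.integer(pattern)
  if (length(pattern) != 4L || anyNA(pattern) ||
      !setequal(pattern, 1:4)) {
    stop("`pattern` must be a permutation of positions 1:4", call. = FALSE)
  }
  successor <- integer(4)
  successor[pattern] <- pattern[c(2:4, 1L)]
  structure(
    list(pattern = pattern, successor = successor),
    class = "asrt_sequence"
  )
}

#' @export
print.asrt_sequence <- function(x, ...) {
  cat("ASRT sequence:", paste(x$pattern, collapse = " - r - "), "- r\n")
  invisible(x)
}

#' @export
format.asrt_sequence <- function(x, ...) paste(x$pattern, collapse = "")

#' Enumerate all 24 ASRT sequence specifications
#'
#' Every ordering of the four positions is a valid ASRT pattern, giving
#' `4! = 24` possible sequences; participants are randomly assigned one.
#'
#' @return A list of 24 [asrt_sequence()] objects.
#' @export
enumerate_sequences <- function() {
  perms <- list()
  for (a in 1:4) for (b in 1:4) for (d in 1:4) for (e in 1:4) {
    p <- c(a, b, d, e)
    if (length(unique(p)) == 4L) perms[[length(perms) + 1L]] <- p
  }
  lapply(perms, asrt_sequence)
}

#' Generate an ASRT stimulus stream
#'
#' Produces the trial-by-trial stimulus positions for one participant:
#' within each block the eight-element template (pattern element, random
#' element, pattern element, ...) repeats `trials_per_block / 8` times.
#' Blocks start with a pattern trial (within-block index 1) and the pattern
#' phase is continuous across blocks. Random trials are uniform over the
#' four positions.
#'
#' @param spec An [asrt_sequence()].
#' @param n_blocks Number of learning blocks (default 25).
#' @param trials_per_block Trials per block; must be a positive multiple
#'   of 8 (default 80, i.e. ten repeats of the template).
#' @param seed Integer seed; the same seed yields an identical stream.
#' @return A tibble with columns `block`, `trial` (1-based within block),
#'   `position` (1-4) and `role` (`"pattern"` or `"random"`).
#' @export
generate_stream <- function(spec, n_blocks = 25L, trials_per_block = 80L,
                            seed = 1L) {
  stopifnot(inherits(spec, "asrt_sequence"))
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 1L) stop("`n_blocks` must be >= 1", call. = FALSE)
  if (trials_per_block < 8L || trials_per_block %% 8L != 0L) {
    stop("`trials_per_block` must be a positive multiple of 8",
         call. = FALSE)
  }
  n <- n_blocks * trials_per_block
  idx <- seq_len(n)
  trial <- ((idx - 1L) %% trials_per_block) + 1L
  block <- ((idx - 1L) %/% trials_per_block) + 1L
  is_pattern <- trial %% 2L == 1L
  # pattern positions cycle through spec$pattern; phase continuous overall
  n_pat <- sum(is_pattern)
  pattern_pos <- spec$pattern[((seq_len(n_pat) - 1L) %% 4L) + 1L]
  position <- integer(n)
  position[is_pattern] <- pattern_pos
  position[!is_pattern] <- with_seed(seed, sample(1:4, n - n_pat, replace = TRUE))
  tibble::tibble(
    block = block,
    trial = trial,
    position = position,
    role = ifelse(is_pattern, "pattern", "random")
  )
}

# Vectorised triplet classification for one block's positions.
# Returns data.frame(triplet, is_trill, is_repetition).
classify_block_positions <- function(pos, successor) {
  n <- length(pos)
  triplet <- rep("unclassifiable", n)
  is_trill <- rep(FALSE, n)
  is_rep <- rep(FALSE, n)
  if (n >= 3L) {
    i <- 3:n
    p0 <- pos[i - 2L]
    p1 <- pos[i - 1L]
    p2 <- pos[i]
    triplet[i] <- ifelse(p2 == successor[p0], "high", "low")
    is_trill[i] <- p0 == p2 & p1 != p2
    is_rep[i] <- p0 == p1 & p1 == p2
  }
  list(triplet = triplet, is_trill = is_trill, is_repetition = is_rep)
}

#' Classify each trial as the third element of a high- or low-probability
#' triplet
#'
#' Trial *n* (third element of the triplet *n-2, n-1, n*) is
#' high-probability when its position equals the pattern successor of the
#' position two trials back; otherwise low-probability. The first two
#' trials of every block cannot be categorised; triplets never span block
#' boundaries. Trills (`x-y-x`) and repetitions (`x-x-x`) are flagged on
#' the trial that closes the triplet.
#'
#' @param trials A data frame with columns `block`, `trial`, `position`
#'   and, when `spec` is `NULL`, `participant_id` and `sequence` (a
#'   four-digit string per participant).
#' @param spec An [asrt_sequence()] applying to all rows, or `NULL` to use
#'   each participant's own `sequence` column.
#' @return `trials` with added columns `triplet`
#'   (`"high"`/`"low"`/`"unclassifiable"`), `is_trill`, `is_repetition`.
#' @export
classify_triplets <- function(trials, spec = NULL) {
  stopifnot(is.data.frame(trials))
  if (!all(c("block", "trial", "position") %in% names(trials))) {
    stop("`trials` needs columns block, trial, position", call. = FALSE)
  }
  pos <- trials$position
  if (anyNA(pos) || !all(pos %in% 1:4)) {
    stop("malformed data: `position` must be in 1..4", call. = FALSE)
  }
  key <- if ("participant_id" %in% names(trials)) {
    paste(trials$participant_id, trials$block)
  } else {
    as.character(trials$block)
  }
  # only the within-block trial order matters for triplet formation
  bad_order <- vapply(
    split(trials$trial, factor(key, unique(key))),
    is.unsorted, logical(1), strictly = TRUE
  )
  if (any(bad_order)) {
    stop("`trials` must be ordered by trial within each block",
         call. = FALSE)
  }
  succ_for <- function(rows) {
    if (!is.null(spec)) return(spec$successor)
    if (!"sequence" %in% names(trials)) {
      stop("no `spec` given and no `sequence` column present", call. = FALSE)
    }
    asrt_sequence(trials$sequence[rows[1L]])$successor
  }
  triplet <- character(nrow(trials))
  is_trill <- logical(nrow(trials))
  is_rep <- logical(nrow(trials))
  for (rows in split(seq_len(nrow(trials)), factor(key, unique(key)))) {
    cl <- classify_block_positions(trials$position[rows], succ_for(rows))
    triplet[rows] <- cl$triplet
    is_trill[rows] <- cl$is_trill
    is_rep[rows] <- cl$is_repetition
  }
  trials$triplet <- triplet
  trials$is_trill <- is_trill
  trials$is_repetition <- is_rep
  trials
}

#' Expected fraction of high-probability triplets
#'
#' Under the ASRT structure, pattern trials (half of all trials) are always
#' the third element of a high-probability triplet, and random trials are
#' with probability 1/4, so the expected high fraction is
#' `0.5 + 0.5 * 0.25 = 0.625`. Under purely random key presses (the PDP
#' generation task's chance level) it is `1/4`.
#'
#' @param mode `"asrt"` or `"pure_random"`.
#' @return The expected proportion of classifiable trials whose triplet is
#'   high-probability.
#' @export
expected_high_fraction <- function(mode = c("asrt", "pure_random")) {
  mode <- match.arg(mode)
  switch(mode, asrt = 0.5 + 0.5 * 0.25, pure_random = 0.25)
}
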