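test_that("sequence space is exactly the 24 orderings of four positions", {
  specs <- enumerate_sequences()
  expect_length(specs, 24L)
  patterns <- vapply(specs, function(s) paste(s$pattern, collapse = ""),
                     character(1))
  expect_length(unique(patterns), 24L)
  for (s in specs) expect_setequal(s$pattern, 1:4)

  # brute force over all 4-tuples from 1:4, keeping permutations
  all_perms <- character()
  for (a in 1:4) for (b in 1:4) for (d in 1:4) for (e in 1:4) {
    if (length(unique(c(a, b, d, e))) == 4) {
      all_perms <- c(all_perms, paste(c(a, b, d, e), collapse = ""))
    }
  }
  expect_setequal(patterns, all_perms)
})

test_that("every successor map is a single 4-cycle", {
  for (s in enumerate_sequences()) {
    succ <- s$successor
    expect_setequal(succ, 1:4) # bijection
    # composing 4 times returns to the start, and no shorter cycle exists
    for (p in 1:4) {
      orbit <- p
      for (k in 1:3) orbit <- c(orbit, succ[orbit[k]])
      expect_setequal(orbit, 1:4)
      expect_equal(succ[orbit[4]], p)
    }
  }
})

test_that("sequence constructor validates and parses", {
  expect_error(asrt_sequence(c(1, 1, 2, 3)), "permutation")
  expect_error(asrt_sequence(c(1, 2, 3)), "permutation")
  expect_equal(asrt_sequence("2431")$pattern, c(2L, 4L, 3L, 1L))
  expect_equal(asrt_sequence(c(2, 4, 3, 1))$successor[2], 4L)
})

test_that("generated streams have the alternating template structure", {
  spec <- asrt_sequence(c(2, 4, 3, 1))
  st <- generate_stream(spec, n_blocks = 25, trials_per_block = 80,
                        seed = 3)
  expect_equal(nrow(st), 2000L)
  expect_equal(unname(table(st$block)), rep(80L, 25L), ignore_attr = TRUE)
  # roles strictly alternate starting with a pattern trial
  expect_true(all(st$role[st$trial %% 2 == 1] == "pattern"))
  expect_true(all(st$role[st$trial %% 2 == 0] == "random"))
  # pattern trials realise the 4-element cycle, i.e. the 8-element
  # template repeats 10 times per 80-trial block
  pat <- st$position[st$role == "pattern"]
  expect_equal(pat, rep(spec$pattern, length.out = length(pat)))

  one <- generate_stream(spec, 1, 8, seed = 9)
  expect_equal(one$position[c(1, 3, 5, 7)], spec$pattern)

  expect_error(generate_stream(spec, 1, 10, seed = 1), "multiple of 8")
  expect_error(generate_stream(spec, 1, 0, seed = 1), "multiple of 8")
  expect_identical(generate_stream(spec, 5, 80, seed = 4),
                   generate_stream(spec, 5, 80, seed = 4))
})

test_that("random trials are uniform over the four positions", {
  spec <- asrt_sequence(c(1, 3, 2, 4))
  st <- generate_stream(spec, n_blocks = 1250, trials_per_block = 80,
                        seed = 17)
  rnd <- st$position[st$role == "random"]
  freqs <- as.vector(table(rnd)) / length(rnd)
  expect_length(freqs, 4L)
  expect_true(all(abs(freqs - 0.25) < 0.01))
})

test_that("triplet classifier agrees with the brute-force oracle on all 64 triples for every sequence", {
  for (spec in enumerate_sequences()) {
    for (a in 1:4) for (b in 1:4) for (c in 1:4) {
      df <- tibble::tibble(block = 1L, trial = 1:3,
                           position = c(a, b, c))
      got <- classify_triplets(df, spec)
      expect_equal(got$triplet[1:2], rep("unclassifiable", 2))
      want <- if (oracle_is_high(a, b, c, spec$pattern)) "high" else "low"
      expect_equal(got$triplet[3], want)
      expect_equal(got$is_trill[3], a == c && b != c)
      expect_equal(got$is_repetition[3], a == b && b == c)
    }
  }
})

test_that("trills and repetitions are mutually exclusive and match the defining shapes", {
  spec <- asrt_sequence(c(1, 2, 3, 4))
  df <- tibble::tibble(block = 1L, trial = 1:5,
                       position = c(1L, 2L, 1L, 1L, 1L))
  got <- classify_triplets(df, spec)
  expect_true(got$is_trill[3])   # 1-2-1
  expect_false(got$is_repetition[3])
  expect_true(got$is_repetition[5]) # 1-1-1
  expect_false(got$is_trill[5])
  expect_false(any(got$is_trill & got$is_repetition))
})

test_that("triplets never span block boundaries", {
  spec <- asrt_sequence(c(2, 1, 3, 4))
  st <- generate_stream(spec, n_blocks = 4, trials_per_block = 16,
                        seed = 5)
  got <- classify_triplets(st, spec)
  expect_true(all(got$triplet[got$trial <= 2] == "unclassifiable"))
  expect_true(all(got$triplet[got$trial > 2] != "unclassifiable"))
})

test_that("pattern trials with classifiable triplets are always high-probability", {
  spec <- asrt_sequence(c(4, 2, 1, 3))
  st <- generate_stream(spec, n_blocks = 10, trials_per_block = 80,
                        seed = 21)
  got <- classify_triplets(st, spec)
  pat <- got$role == "pattern" & got$triplet != "unclassifiable"
  expect_true(all(got$triplet[pat] == "high"))
})

test_that("triplet labels are equivariant under position relabelling", {
  perms <- list(c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1), c(2, 3, 4, 1))
  spec <- asrt_sequence(c(2, 4, 3, 1))
  st <- generate_stream(spec, n_blocks = 3, trials_per_block = 40,
                        seed = 31)
  base <- classify_triplets(st, spec)
  for (pi in perms) {
    st2 <- st
    st2$position <- pi[st$position]
    spec2 <- asrt_sequence(pi[spec$pattern])
    got <- classify_triplets(st2, spec2)
    expect_equal(got$triplet, base$triplet)
    expect_equal(got$is_trill, base$is_trill)
    expect_equal(got$is_repetition, base$is_repetition)
  }
})

test_that("classifier rejects malformed positions and disordered blocks", {
  spec <- asrt_sequence(c(1, 2, 3, 4))
  df <- tibble::tibble(block = 1L, trial = 1:3, position = c(1L, 5L, 2L))
  expect_error(classify_triplets(df, spec), "1..4")
  df2 <- tibble::tibble(block = 1L, trial = c(2L, 1L, 3L),
                        position = c(1L, 2L, 3L))
  expect_error(classify_triplets(df2, spec), "ordered")
})

test_that("expected high fractions match the design arithmetic", {
  # pattern trials (1/2 of trials) always high; random trials high 1/4
  expect_identical(expected_high_fraction("asrt"), 0.5 + 0.5 * 0.25)
  expect_identical(expected_high_fraction("asrt"), 0.625)
  expect_identical(expected_high_fraction("pure_random"), 0.25)
  expect_identical(1 - expected_high_fraction("asrt"), 0.375)
  expect_error(expected_high_fraction("other"))
})
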