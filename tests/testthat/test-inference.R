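# independent split-plot sums of squares, computed from the definitions
splitplot_oracle <- function(d) {
  # d: data.frame(y, w, b, id), balanced
  m <- mean(d$y)
  W <- nlevels(factor(d$w))
  ids <- unique(d$id)
  g_of <- tapply(as.character(d$b), d$id, function(x) x[1])
  S <- tapply(d$y, d$id, mean)
  G <- tapply(d$y, d$b, mean)
  n_g <- table(g_of[ids])
  Wm <- tapply(d$y, d$w, mean)
  C <- tapply(d$y, list(d$b, d$w), mean)

  ss_b <- W * sum(n_g * (G[names(n_g)] - m)^2)
  ss_subj <- W * sum((S[ids] - G[g_of[ids]])^2)
  ss_w <- length(ids) * sum((Wm - m)^2)
  ss_int <- 0
  for (g in rownames(C)) for (w in colnames(C)) {
    ss_int <- ss_int + n_g[[g]] * (C[g, w] - G[[g]] - Wm[[w]] + m)^2
  }
  ss_res <- 0
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    ss_res <- ss_res +
      (r$y - C[as.character(r$b), as.character(r$w)] -
         S[[as.character(r$id)]] + G[[as.character(r$b)]])^2
  }
  n_id <- length(ids); n_grp <- length(n_g)
  list(
    between = (ss_b / (n_grp - 1)) / (ss_subj / (n_id - n_grp)),
    within = (ss_w / (W - 1)) / (ss_res / ((n_id - n_grp) * (W - 1))),
    interaction = (ss_int / ((n_grp - 1) * (W - 1))) /
      (ss_res / ((n_id - n_grp) * (W - 1)))
  )
}

test_that("one-sample t matches the closed form on a hand-computed case", {
  tt <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(tt$t, 2 * sqrt(3) / 1)
  expect_equal(tt$df, 2L)
  expect_equal(tt$mean, 2)
  expect_equal(tt$sd, 1)
})

test_that("one-sample t agrees with the reference implementation on random fixtures", {
  set.seed(19)
  for (rep in 1:20) {
    x <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0.5, 4))
    mu0 <- runif(1, -2, 2)
    mine <- one_sample_t(x, mu0)
    ref <- stats::t.test(x, mu = mu0)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("one-sample t is translation invariant and p is sign-symmetric", {
  set.seed(4)
  x <- rnorm(12, 3, 2)
  a <- one_sample_t(x, 1)
  b <- one_sample_t(x + 10, 11)
  expect_equal(a$t, b$t)
  expect_equal(a$p, b$p)
  flipped <- one_sample_t(2 * 1 - x, 1) # reflect values about mu0
  expect_equal(flipped$t, -a$t)
  expect_equal(flipped$p, a$p)
})

test_that("zero-variance samples yield the degenerate markers", {
  same <- one_sample_t(rep(5, 6), 5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  off <- one_sample_t(rep(5, 6), 4)
  expect_equal(off$t, Inf)
  expect_equal(off$p, 0)
  below <- one_sample_t(rep(3, 6), 4)
  expect_equal(below$t, -Inf)
  expect_error(one_sample_t(c(1), 0), ">= 2")
  expect_error(one_sample_t(c(1, Inf), 0), "finite")
})

test_that("group descriptives match hand arithmetic and ignore order", {
  d <- group_descriptives(c(10, 20), c("a", "a"))
  expect_equal(d$mean, 15)
  expect_equal(d$sd, sqrt(50), tolerance = 1e-12)
  expect_equal(d$sem, 5)
  expect_equal(d$median, 15)

  two <- group_descriptives(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(two[two$group == "a", -1], two[two$group == "b", -1])

  v <- c(3, 1, 4, 1, 5); g <- c("x", "y", "x", "y", "x")
  perm <- sample(5)
  expect_equal(group_descriptives(v, g),
               group_descriptives(v[perm], g[perm]))

  expect_warning(
    group_descriptives(c(1, 2, NA), factor(c("a", "a", "b"))),
    "empty"
  )
})

test_that("mixed ANOVA agrees with the sums-of-squares oracle", {
  set.seed(77)
  for (rep in 1:5) {
    d <- expand.grid(id = paste0("s", 1:10), w = c("u1", "u2", "u3"),
                     stringsAsFactors = FALSE)
    d$b <- ifelse(as.integer(sub("s", "", d$id)) <= 5, "g1", "g2")
    d$y <- rnorm(nrow(d), 400, 30) + (d$b == "g2") * 25 +
      (d$w == "u3") * -15 + (d$b == "g2" & d$w == "u2") * 8
    got <- mixed_anova(d, "y", "w", "b", "id")
    ora <- splitplot_oracle(d)
    expect_equal(got$F[got$effect == "between"], ora$between,
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "within"], ora$within,
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "interaction"], ora$interaction,
                 tolerance = 1e-8)
    expect_true(all(got$p >= 0 & got$p <= 1))
    expect_true(all(got$pes >= 0 & got$pes <= 1))
  }
})

test_that("constant responses give F = 0 and zero interaction on additive plants", {
  d <- expand.grid(id = paste0("s", 1:8), w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$b <- rep(c("g1", "g2"), each = 4)[match(d$id, paste0("s", 1:8))]
  d$y <- 7
  got <- mixed_anova(d, "y", "w", "b", "id")
  expect_equal(got$F, rep(0, 3))
  expect_equal(got$p, rep(1, 3))

  # additive plant: subject offsets + main effects, plus residuals that
  # cancel within every cell and every subject, so the cell means stay
  # exactly additive -> interaction F exactly zero, other Fs finite
  d2 <- d
  subj_eff <- setNames(seq(0, 14, by = 2), paste0("s", 1:8))
  eps_sign <- setNames(rep(c(3, -3), 4), paste0("s", 1:8))
  d2$y <- subj_eff[d2$id] + (d2$w == "b") * 5 + (d2$b == "g2") * 3 +
    eps_sign[d2$id] * ifelse(d2$w == "b", -1, 1)
  got2 <- mixed_anova(d2, "y", "w", "b", "id")
  expect_equal(got2$F[got2$effect == "interaction"], 0)
  expect_true(is.finite(got2$F[got2$effect == "within"]))
})

test_that("degenerate within-cell variance is flagged, not reported as a number", {
  d <- expand.grid(id = paste0("s", 1:4), w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$b <- rep(c("g1", "g2"), 2)[match(d$id, paste0("s", 1:4))]
  d$y <- (d$b == "g2") * 10 + (d$w == "b") * 20 +
    (d$b == "g2" & d$w == "b") * 40
  expect_error(mixed_anova(d, "y", "w", "b", "id"), "degenerate")
})

test_that("unbalanced designs are rejected with the offending cells named", {
  d <- expand.grid(id = paste0("s", 1:6), w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$b <- rep(c("g1", "g2"), each = 3)[match(d$id, paste0("s", 1:6))]
  d$y <- rnorm(nrow(d))
  expect_error(mixed_anova(d[-1, ], "y", "w", "b", "id"),
               "unbalanced.*s1", ignore.case = TRUE)
})

test_that("a pure between-group offset is detected and the null interaction retained", {
  set.seed(55)
  n_sims <- 50
  detected <- logical(n_sims)
  retained <- logical(n_sims)
  for (k in seq_len(n_sims)) {
    d <- expand.grid(id = paste0("s", 1:30), w = paste0("u", 1:5),
                     stringsAsFactors = FALSE)
    d$b <- ifelse(as.integer(sub("s", "", d$id)) <= 15, "g1", "g2")
    subj <- setNames(rnorm(30, 0, 15), paste0("s", 1:30))
    d$y <- 400 + subj[d$id] + (d$b == "g2") * 30 + rnorm(nrow(d), 0, 20)
    got <- mixed_anova(d, "y", "w", "b", "id")
    detected[k] <- got$p[got$effect == "between"] < 0.05
    retained[k] <- got$p[got$effect == "interaction"] > 0.05
  }
  expect_gte(mean(detected), 0.9)
  expect_gte(mean(retained), 0.9)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.4), 3), c(0.03, 1))
  expect_equal(bonferroni(0.2), 0.2)
})
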