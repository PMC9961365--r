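#' One-sample t test
#'
#' Classical one-sample t statistic `t = (mean(x) - mu0) * sqrt(n) / sd(x)`
#' with a two-sided p value from the t distribution on `n - 1` degrees of
#' freedom. With zero variance, the statistic is 0 (p = 1) when the mean
#' equals `mu0` and signed infinite (p = 0) otherwise.
#'
#' @param values Numeric vector, `n >= 2`, finite.
#' @param mu0 Null mean (default 0).
#' @return A list of class `ttest_result`: `t`, `df`, `p`, `mean`, `sd`,
#'   `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be >= 2 finite numbers", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    t <- if (m == mu0) 0 else sign(m - mu0) * Inf
    p <- if (m == mu0) 1 else 0
  } else {
    t <- (m - mu0) * sqrt(n) / s
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  structure(list(t = t, df = n - 1L, p = p, mean = m, sd = s, n = n),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("one-sample t: t(%d) = %.3f, p = %.4g, mean = %.3f (sd %.3f, n %d)\n",
              x$df, x$t, x$p, x$mean, x$sd, x$n))
  invisible(x)
}

#' Descriptive statistics by group
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length.
#' @return A tibble `group`, `n`, `mean`, `sd`, `median`, `sem`. Empty
#'   groups are omitted with a warning.
#' @export
group_descriptives <- function(values, group) {
  stopifnot(length(values) == length(group))
  group <- as.factor(group)
  empty <- setdiff(levels(group), unique(as.character(group[!is.na(values)])))
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(values)
  d <- tibble::tibble(group = as.character(group[keep]),
                      value = values[keep])
  grp <- dplyr::group_by(d, .data$group)
  dplyr::summarise(
    grp,
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    median = stats::median(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' Mixed-design (split-plot) ANOVA
#'
#' Fits the standard mixed-design ANOVA with one within-subjects factor
#' and one between-subjects factor via `stats::aov` with an
#' `Error(participant/within)` stratum structure, and reports F, degrees
#' of freedom, p and partial eta squared for the between main effect, the
#' within main effect and their interaction. The design must be balanced
#' (every participant measured once per within level); unbalanced input
#' raises an error naming the offending cells. Sums of squares are
#' sequential, which coincides with all other types on balanced designs.
#' No sphericity correction is computed by the delegated routine; the
#' returned `sphericity_note` attribute records that the dfs are
#' uncorrected.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param within Name of the within-subjects factor column.
#' @param between Name of the between-subjects factor column.
#' @param id Name of the participant identifier column.
#' @return A tibble `effect`, `df1`, `df2`, `F`, `p`, `pes` with
#'   attributes `ss_type` and `sphericity_note`.
#' @export
mixed_anova <- function(data, dv, within, between, id) {
  d <- data.frame(
    .y = data[[dv]],
    .w = factor(data[[within]]),
    .b = factor(data[[between]]),
    .id = factor(data[[id]])
  )
  if (anyNA(d)) stop("mixed_anova: missing values in design or response",
                     call. = FALSE)
  # balance: each participant exactly once per within level
  tab <- table(d$.id, d$.w)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    cells <- apply(bad, 1L, function(ix) {
      paste0(rownames(tab)[ix[1]], " x ", colnames(tab)[ix[2]],
             " (n=", tab[ix[1], ix[2]], ")")
    })
    stop("unbalanced design; offending cells: ",
         paste(utils::head(cells, 5L), collapse = ", "), call. = FALSE)
  }
  # each participant in exactly one between group
  if (any(rowSums(table(d$.id, d$.b) > 0) != 1L)) {
    stop("each participant must belong to exactly one between-subjects group",
         call. = FALSE)
  }
  fit <- stats::aov(.y ~ .b * .w + Error(.id / .w), data = d)
  sm <- summary(fit)
  get_stratum <- function(name) as.data.frame(sm[[name]][[1]])
  s_between <- get_stratum("Error: .id")
  s_within <- get_stratum("Error: .id:.w")

  pull_effect <- function(stratum, label, effect_name) {
    rn <- trimws(rownames(stratum))
    i <- match(label, rn)
    r <- match("Residuals", rn)
    ss_e <- stratum$`Sum Sq`[i]
    ss_r <- stratum$`Sum Sq`[r]
    tol <- 1e-10 * max(1, abs(ss_e) + abs(ss_r))
    if (ss_r <= tol && ss_e <= tol) {
      f <- 0; p <- 1; pes <- 0
    } else if (ss_r <= tol) {
      stop("degenerate within-cell variance for effect '", effect_name,
           "'; F is not defined", call. = FALSE)
    } else {
      f <- (ss_e / stratum$Df[i]) / (ss_r / stratum$Df[r])
      p <- stats::pf(f, stratum$Df[i], stratum$Df[r], lower.tail = FALSE)
      pes <- ss_e / (ss_e + ss_r)
    }
    tibble::tibble(effect = effect_name, df1 = stratum$Df[i],
                   df2 = stratum$Df[r], F = f, p = p, pes = pes)
  }

  out <- dplyr::bind_rows(
    pull_effect(s_between, ".b", "between"),
    pull_effect(s_within, ".w", "within"),
    pull_effect(s_within, ".b:.w", "interaction")
  )
  attr(out, "ss_type") <-
    "sequential (aov); equals Type II/III on the enforced balanced design"
  attr(out, "sphericity_note") <-
    "uncorrected degrees of freedom (no sphericity correction available)"
  out
}

#' Bonferroni correction
#'
#' Multiplies p values by the number of comparisons, capping at 1.
#'
#' @param p Numeric vector of p values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, p * m)
}
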