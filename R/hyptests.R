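#' Migrant-pool resampling null for community mean rrn
#'
#' Tests whether an observed community mean copy number could arise from
#' random assembly out of the shared genus pool: draws `n_draw` OTU copy
#' numbers from the pool `n_rep` times (without replacement by default),
#' records each sample's mean, and computes a two-sided empirical p-value
#' as the add-one fraction of resampled means at least as far from the
#' null-distribution mean as the observed value, so p is never 0.
#'
#' @param pool_rrn integer copy numbers (1-15) of the migrant pool, one per
#'   OTU.
#' @param observed_mean the observed community mean copy number.
#' @param n_draw OTUs per resample (default 150).
#' @param n_rep number of resamples (default 1000).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param replace draw with replacement instead (default `FALSE`).
#' @return Object of class `null_distribution`: `draws`, `observed`,
#'   `empirical_p`, `n_draw`, `n_rep`, `seed`.
#' @export
migrant_pool_null <- function(pool_rrn, observed_mean, n_draw = 150,
                              n_rep = 1000, seed, replace = FALSE) {
  pool_rrn <- as.numeric(pool_rrn)
  if (any(!is.finite(pool_rrn))) stopf("'pool_rrn' must be finite")
  assert_scalar_number(observed_mean, "observed_mean")
  if (n_draw < 1 || !is_wholenumber(n_draw)) stopf("'n_draw' must be a positive integer")
  if (n_rep < 1 || !is_wholenumber(n_rep)) stopf("'n_rep' must be a positive integer")
  if (!replace && length(pool_rrn) < n_draw)
    stopf("pool size %d is smaller than n_draw = %d", length(pool_rrn), n_draw)
  n_draw <- as.integer(n_draw); n_rep <- as.integer(n_rep)
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_rep), function(i)
      mean(sample(pool_rrn, n_draw, replace = replace)), numeric(1))
  })
  center <- mean(draws)
  p <- (1 + sum(abs(draws - center) >= abs(observed_mean - center))) /
    (n_rep + 1)
  structure(list(draws = draws, observed = observed_mean, empirical_p = p,
                 n_draw = n_draw, n_rep = n_rep, seed = as.integer(seed),
                 replace = replace),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Migrant-pool null: observed mean rrn = %.4g vs %d resamples of %d (null mean %.4g, sd %.4g); empirical p = %.4g\n",
              x$observed, x$n_rep, x$n_draw, mean(x$draws),
              stats::sd(x$draws), x$empirical_p))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise contrasts
#'
#' Fixed-effects one-way ANOVA (via [stats::aov()]) plus all pairwise
#' comparisons adjusted by Tukey's honest significant difference
#' (studentized-range distribution). Zero within-group variance with a
#' real between-group difference is reported as the smallest representable
#' positive p with a warning, not an error.
#'
#' @param groups named list of numeric vectors, one per group; at least 2
#'   groups of at least 2 observations each.
#' @return List of class `anova_tukey` with `omnibus` (`statistic` = F,
#'   `p_value`, `df`, `group_sizes`, `method`) and `pairwise` (data.frame
#'   with `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("'groups' must be a list of at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stopf("every group needs at least 2 observations (group '%s' has %d)",
          names(groups)[sizes < 2L][1L], min(sizes))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  ss_between <- an[1L, "Sum Sq"]; ss_within <- an[2L, "Sum Sq"]
  Fv <- an[1L, "F value"]; p <- an[1L, "Pr(>F)"]

  degenerate <- is.finite(ss_within) && ss_within <= 1e-12 * max(ss_between, 1)
  if (degenerate) {
    warnf("zero within-group variance; p-values degenerate")
    if (ss_between > 0) {
      Fv <- Inf; p <- .Machine$double.xmin
    } else {
      Fv <- 0; p <- 1
    }
  }
  if (!is.finite(p)) p <- 1
  p <- min(max(p, .Machine$double.xmin), 1)

  tk <- stats::TukeyHSD(fit)$group
  pw <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
  if (degenerate)
    pw$p_adj <- ifelse(abs(pw$diff) > 0, .Machine$double.xmin, 1)
  pw$p_adj <- pmin(pmax(pw$p_adj, .Machine$double.xmin), 1)

  structure(list(
    omnibus = list(statistic = Fv, p_value = p,
                   df = unname(an[, "Df"]), group_sizes = as.integer(sizes),
                   method = "one-way ANOVA"),
    pairwise = pw
  ), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$omnibus$df[1L], x$omnibus$df[2L],
              x$omnibus$statistic, x$omnibus$p_value))
  cat("Tukey HSD contrasts:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Mann-Whitney U test with exact small-sample path
#'
#' Rank-sum test with midrank tie handling. For a combined sample size of
#' at most `exact_limit` the two-sided p-value is computed by exhaustive
#' enumeration of all group-label assignments over the (mid)ranks — a
#' permutation test that is valid with ties. Otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used; all-tied data yield p = 1 (variance 0), never an error.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   default (`NULL`) enumerates when `length(x) + length(y) <= exact_limit`.
#' @param exact_limit switch-over size for automatic enumeration
#'   (default 12).
#' @return List of class `test_result`: `statistic` (U for `x`),
#'   `p_value`, `method`, `group_sizes`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y, exact = NULL, exact_limit = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stopf("'x' and 'y' must be non-empty")
  if (any(!is.finite(c(x, y)))) stopf("inputs must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  use_exact <- exact %||% (N <= exact_limit)

  if (use_exact) {
    combs <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    ties <- table(c(x, y))
    v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- max(abs(U - mu) - 0.5, 0) / sqrt(v)
      p <- min(2 * stats::pnorm(-z), 1)
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  structure(list(statistic = U,
                 p_value = min(max(p, .Machine$double.xmin), 1),
                 method = method, group_sizes = c(n1, n2)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, n = (%s), p = %.4g\n", x$method,
              x$statistic, paste(x$group_sizes, collapse = ", "), x$p_value))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests and clips at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) < 1L)
    stopf("'p_values' must be a non-empty numeric vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}
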