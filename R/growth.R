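#' Logistic growth curve, Zwietering parameterization
#'
#' `A / (1 + exp(4 * mu_max * (lag - t) / A + 2))`. In this form `mu_max`
#' is the maximum slope of the curve (units of value per day) and `lag` is
#' the intercept of the tangent line at the inflection with the time axis,
#' i.e. the lag phase in days. `A` is the asymptotic value.
#'
#' @param t time vector (days).
#' @param A asymptote (> 0).
#' @param mu_max maximum growth rate (> 0).
#' @param lag lag phase (>= 0, days).
#' @return Curve values at `t`.
#' @export
logistic_zwietering <- function(t, A, mu_max, lag) {
  A / (1 + exp(4 * mu_max * (lag - t) / A + 2))
}

#' Fit the logistic growth model to a cell-count time series
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds, via
#' [minpack.lm::nlsLM()]) of the Zwietering logistic, giving the asymptote
#' `A`, maximum growth rate `mu_max` and lag phase `lag` directly as
#' parameters. Starting values default to `A0 = max(y)`, `mu0` = the
#' largest finite-difference slope, and `lag0` the time of that slope minus
#' `A0 / (2 * mu0)`, clipped at 0. On failure the fit is retried from
#' seeded, jittered starts; if nothing converges the best parameters so far
#' are returned with `converged = FALSE`, never an error.
#'
#' @param time strictly increasing non-negative times (days); at least 5.
#' @param value non-negative observations (counts or cells per area).
#' @param init optional named list/vector with `A`, `mu_max`, `lag`.
#' @param n_restarts jittered restarts on failure (default 5).
#' @param seed seed for the restart jitter.
#' @param log_transform fit on `log(value)` (requires positive values).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return Object of class `growth_fit`: list with `A`, `mu_max`, `lag`,
#'   `rss`, `converged`, `n_obs`, `fitted`, `time`, `value`.
#' @export
#' @examples
#' t <- seq(0, 20, length.out = 20)
#' y <- logistic_zwietering(t, A = 100, mu_max = 5, lag = 2)
#' fit_logistic(t, y)
fit_logistic <- function(time, value, init = NULL, n_restarts = 5,
                         seed = 1L, log_transform = FALSE, max_iter = 500) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value)) stopf("'time' and 'value' lengths differ")
  if (length(time) < 5L) stopf("fit refused: need at least 5 observations")
  if (any(diff(time) <= 0)) stopf("'time' must be strictly increasing")
  if (any(!is.finite(time)) || any(!is.finite(value)) || any(value < 0))
    stopf("'value' must be finite and non-negative")
  y <- value
  if (log_transform) {
    if (any(value <= 0)) stopf("log_transform requires positive values")
    y <- log(value)
  }

  if (is.null(init)) {
    A0 <- max(value)
    if (A0 <= 0) A0 <- 1
    slopes <- diff(value) / diff(time)
    mu0 <- max(slopes)
    if (!is.finite(mu0) || mu0 <= 0) mu0 <- A0 / diff(range(time))
    t_star <- time[which.max(slopes)]
    lag0 <- max(0, t_star - A0 / (2 * mu0))
    init <- c(A = A0, mu_max = mu0, lag = lag0)
  } else {
    init <- unlist(init)[c("A", "mu_max", "lag")]
  }
  lower <- c(A = 1e-8, mu_max = 1e-8, lag = 0)
  start0 <- pmax(init, lower * 2)

  model <- if (log_transform) {
    y ~ log(A / (1 + exp(4 * mu_max * (lag - t) / A + 2)))
  } else {
    y ~ A / (1 + exp(4 * mu_max * (lag - t) / A + 2))
  }
  dat <- data.frame(t = time, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-15,
                                     ptol = 1e-12)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(model, data = dat, start = as.list(start),
                        lower = lower, control = ctrl),
      error = function(e) NULL)
  }

  starts <- list(start0)
  jit <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_restarts), function(i)
      pmax(start0 * exp(stats::rnorm(3, 0, 0.5)), lower * 2))
  })
  starts <- c(starts, jit)

  best <- NULL; best_rss <- Inf; converged <- FALSE
  for (s in starts) {
    f <- try_fit(s)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (rss < best_rss) {
      best <- stats::coef(f); best_rss <- rss; converged <- TRUE
    }
    if (converged && rss <= best_rss) next
  }
  if (is.null(best)) {
    best <- start0
    best_rss <- sum((y - do.call(logistic_zwietering,
                                 c(list(time), as.list(start0))))^2)
  }
  A <- unname(best["A"]); mu <- unname(best["mu_max"]); lag <- unname(best["lag"])
  # degenerate fits (no signal, lag beyond the series, rate at its bound)
  # are flagged rather than trusted
  if (lag >= max(time) || mu <= 2 * lower["mu_max"]) converged <- FALSE
  fitted <- logistic_zwietering(time, A, mu, lag)
  structure(list(A = A, mu_max = mu, lag = lag, rss = best_rss,
                 converged = converged, n_obs = length(time),
                 fitted = fitted, time = time, value = value),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit (n = %d): A = %.4g, mu_max = %.4g, lag = %.4g d, RSS = %.4g%s\n",
              x$n_obs, x$A, x$mu_max, x$lag, x$rss,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

ols_result <- function(fit, xname = "x") {
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # exact fits are legitimate inputs here (noiseless oracles)
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- stats::coef(sm)
  r2 <- sm$r.squared
  p <- unname(co[2L, 4L])
  yv <- stats::model.response(stats::model.frame(fit))
  # a (numerically) constant response explains nothing: R^2 = 0, p = 1,
  # rather than the 0/0 round-off ratio lm would report
  if (stats::var(yv) <= .Machine$double.eps^0.5 * max(1, mean(yv)^2)) {
    r2 <- 0; p <- 1
  }
  if (!is.finite(r2)) r2 <- 0
  if (!is.finite(p)) p <- 1
  structure(list(
    slope = unname(co[2L, 1L]),
    intercept = unname(co[1L, 1L]),
    r_squared = r2,
    p_value = max(p, .Machine$double.xmin),
    n = length(stats::fitted(fit)),
    ci95_band = function(newx) {
      nd <- stats::setNames(data.frame(newx), xname)
      as.data.frame(stats::predict(fit, newdata = nd,
                                   interval = "confidence", level = 0.95))
    },
    fit = fit
  ), class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g, intercept = %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Regress a community trait ratio on a growth parameter
#'
#' Simple OLS of time-averaged HCN:LCN ratios against fitted growth
#' parameters (lag phase or maximum growth rate), with the two-sided slope
#' t-test p-value and a 95% confidence band for the mean response.
#'
#' @param x growth-parameter values (one per experimental unit).
#' @param y trait values (same length, >= 3, no `NA`).
#' @return Object of class `ols_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and `ci95_band(newx)` giving the fitted
#'   mean and its 95% confidence limits.
#' @export
regress_trait_growth <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("'x' and 'y' lengths differ")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (anyNA(x) || anyNA(y)) stopf("undefined (NA) values are not admissible")
  if (stats::var(x) == 0) stopf("degenerate predictor: zero variance in x")
  ols_result(stats::lm(y ~ x, data = data.frame(x = x, y = y)), "x")
}

#' OLS linear trend of an abundance series over time
#'
#' Same machinery as [regress_trait_growth()], for per-rrn-class abundance
#' versus succession time.
#'
#' @param time time values (days).
#' @param y abundances.
#' @return An `ols_result`, see [regress_trait_growth()].
#' @export
fit_linear_trend <- function(time, y) {
  regress_trait_growth(time, y)
}
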