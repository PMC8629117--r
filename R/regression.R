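# Simple-linear-regression core shared by the window search, the climate
# sensitivity profile and the evaluation stage. Fits are closed-form OLS so
# the exhaustive search can reuse the identical arithmetic in vectorized
# form; stats::lm is used as an independent cross-check in the test suite.

#' Ordinary least-squares fit of event day on a scalar cue
#'
#' @param x Numeric cue values (one per year).
#' @param y Numeric event days (same length).
#' @return An object of class `pc_linfit`: a list with elements `intercept`,
#'   `slope`, `slope_se`, `r2` (multiple), `r2_adj` (adjusted), `n`,
#'   `sigma2` (residual variance, denominator `n - 2`), `x_mean`, `sxx`,
#'   `rss`, `fitted`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations to fit a line (got ", n, ")")
  if (anyNA(x) || anyNA(y)) stop("missing values in regression data")
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  if (sxx <= .Machine$double.eps * n * max(1, xm^2))
    stop("degenerate predictor: cue has zero variance")
  sxy <- sum((x - xm) * (y - ym))
  syy <- sum((y - ym)^2)
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  rss <- syy - slope * sxy
  rss <- max(rss, 0)
  sigma2 <- rss / (n - 2)
  r2 <- if (syy > 0) 1 - rss / syy else 0
  structure(list(
    intercept = intercept, slope = slope,
    slope_se = sqrt(sigma2 / sxx),
    r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    n = n, sigma2 = sigma2, x_mean = xm, sxx = sxx, rss = rss,
    fitted = unname(intercept + slope * x)
  ), class = "pc_linfit")
}

#' @export
print.pc_linfit <- function(x, ...) {
  cat(sprintf(
    "<pc_linfit> n=%d  intercept=%.3f  slope=%.3f (SE %.3f)  R2=%.3f adj=%.3f\n",
    x$n, x$intercept, x$slope, x$slope_se, x$r2, x$r2_adj))
  invisible(x)
}

# Gaussian maximum-likelihood AICc from a residual sum of squares.
# k counts estimated parameters including the residual variance.
aicc_from_rss <- function(rss, n, k) {
  if (any(n - k - 1 <= 0))
    stop("AICc undefined: n - k - 1 <= 0 (n = ", n[1], ", k = ", k, ")")
  sigma2_ml <- rss / n
  m2ll <- n * (log(2 * pi * sigma2_ml) + 1)
  m2ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample-corrected Akaike information criterion
#'
#' AICc = -2 log L + 2k + 2k(k+1)/(n-k-1), with the Gaussian maximum
#' likelihood and `k` counting the estimated coefficients plus the residual
#' variance (so an intercept-only model has k = 2 and a slope model k = 3).
#'
#' @param fit A `pc_linfit` from [fit_linear()], or a numeric response
#'   vector, in which case the intercept-only baseline model is scored.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  if (inherits(fit, "pc_linfit")) {
    aicc_from_rss(fit$rss, fit$n, k = 3)
  } else if (is.numeric(fit)) {
    n <- length(fit)
    aicc_from_rss(sum((fit - mean(fit))^2), n, k = 2)
  } else stop("aicc() expects a pc_linfit or a numeric response vector")
}

#' Normal-theory prediction interval for a new cue value
#'
#' Classical interval for a single new observation:
#' `yhat +/- t(n-2, (1+level)/2) * s * sqrt(1 + 1/n + (x_new - xbar)^2 / Sxx)`.
#'
#' @param fit A `pc_linfit`.
#' @param x_new Numeric vector of new cue values.
#' @param level Coverage probability in (0, 1); default 0.95.
#' @return A data frame with columns `predicted`, `pi_low`, `pi_high`.
#' @export
prediction_interval <- function(fit, x_new, level = 0.95) {
  stopifnot(inherits(fit, "pc_linfit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be a probability strictly between 0 and 1")
  yhat <- fit$intercept + fit$slope * x_new
  tq <- stats::qt((1 + level) / 2, df = fit$n - 2)
  half <- tq * sqrt(fit$sigma2) *
    sqrt(1 + 1 / fit$n + (x_new - fit$x_mean)^2 / fit$sxx)
  data.frame(predicted = yhat, pi_low = yhat - half, pi_high = yhat + half)
}
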