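# Climate sensitivity profile (CSP).
#
# For every lag day before the reference day, event day is regressed on
# that single day's mean temperature. The per-lag slope and R-squared
# profiles are smoothed with a penalized regression spline (mgcv, smoothing
# parameter by GCV). The critical window is the longest run of consecutive
# lags on which the smoothed coefficient lies in its extreme 2.5% tail
# (lower tail for a negative, upper for a positive temperature effect) and
# the smoothed R-squared lies at or above its 97.5% quantile. The cue is
# then the mean temperature over that window.

#' Per-lag simple regressions of event day on daily temperature
#'
#' @param phenology A [pheno_series()].
#' @param matrix A `climate_matrix` covering the phenology years.
#' @return A data frame with columns `lag`, `coef` (days per degree C) and
#'   `r2` (multiple R-squared), one row per lag. Lags with (numerically)
#'   constant temperature across years are recorded as coef 0, r2 0 with a
#'   warning.
#' @export
daily_regressions <- function(phenology, matrix) {
  stopifnot(inherits(phenology, "pheno_series"),
            inherits(matrix, "climate_matrix"))
  if (nrow(phenology) < 4) stop("need at least 4 years for daily regressions")
  matrix <- subset_years(matrix, phenology$year)
  y <- as.numeric(phenology$event_day)
  X <- unclass(matrix)
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  # centered arithmetic so the profile is invariant to a uniform
  # temperature shift up to rounding
  Xc <- sweep(X, 2, colMeans(X))
  sxy <- as.vector(crossprod(Xc, yc))
  sxx <- colSums(Xc^2)
  degenerate <- sxx <= .Machine$double.eps * n * pmax(1, colMeans(X)^2)
  coef <- ifelse(degenerate, 0, sxy / sxx)
  r2 <- ifelse(degenerate, 0,
               ifelse(syy > 0, 1 - pmax(syy - coef * sxy, 0) / syy, 0))
  if (any(degenerate))
    warning(sum(degenerate), " lag(s) with constant temperature: coef and ",
            "r2 recorded as 0")
  data.frame(lag = attr(matrix, "lags"), coef = coef, r2 = r2)
}

#' Smooth a per-lag profile with a penalized regression spline
#'
#' Penalized cubic regression spline of value against lag, with the
#' smoothing parameter chosen by generalized cross-validation.
#'
#' @param values Numeric per-lag series.
#' @param lags Integer lags (same length); default `seq_along(values)`.
#' @param basis_dim Spline basis dimension (default 50).
#' @return Numeric vector of fitted (smoothed) values at every lag.
#' @export
smooth_profile <- function(values, lags = seq_along(values), basis_dim = 50) {
  if (length(values) < 10) stop("need at least 10 lags to smooth a profile")
  if (basis_dim >= length(values))
    stop("basis_dim must be smaller than the number of lags")
  df <- data.frame(v = values, lag = as.numeric(lags))
  fit <- mgcv::gam(v ~ s(lag, k = basis_dim, bs = "cr"), data = df,
                   method = "GCV.Cp")
  as.numeric(stats::fitted(fit))
}

#' Build a climate sensitivity profile
#'
#' Runs [daily_regressions()], smooths both profiles, computes the quantile
#' thresholds and extracts the critical window.
#'
#' @inheritParams daily_regressions
#' @param include_reference_day Keep lag 0 (the reference day itself) in the
#'   profile? Default `FALSE`: the profile starts the day before the
#'   reference day.
#' @param basis_dim Basis dimension for the smoother (default 50).
#' @param coef_tail `"auto"` (tail chosen by the sign of the median smoothed
#'   coefficient), `"lower"` or `"upper"`.
#' @param lower_q,upper_q Tail probabilities for the coefficient and
#'   R-squared thresholds (defaults 0.025 and 0.975).
#' @param relax If `TRUE` and no lag passes both thresholds at the
#'   requested tails, the tails are widened step by step
#'   (0.05/0.95, 0.1/0.9, 0.25/0.75) until a window emerges; the tails
#'   actually used are recorded in the result. Default `FALSE` (an empty
#'   window is an error).
#' @return An object of class `pc_csp_profile`: list with `profile` (data
#'   frame lag, coef, r2, coef_smooth, r2_smooth, in_window), `coef_threshold`,
#'   `r2_threshold`, `coef_tail`, `critical` (list open, close) and
#'   `reference_day`.
#' @export
csp_profile <- function(phenology, matrix, include_reference_day = FALSE,
                        basis_dim = 50, coef_tail = c("auto", "lower", "upper"),
                        lower_q = 0.025, upper_q = 0.975, relax = FALSE) {
  coef_tail <- match.arg(coef_tail)
  if (!include_reference_day && 0L %in% attr(matrix, "lags")) {
    keep <- attr(matrix, "lags") != 0L
    matrix <- structure(unclass(matrix)[, keep, drop = FALSE],
                        class = c("climate_matrix", "matrix"),
                        years = attr(matrix, "years"),
                        lags = attr(matrix, "lags")[keep],
                        reference_day = attr(matrix, "reference_day"))
  }
  prof <- daily_regressions(phenology, matrix)
  prof$coef_smooth <- smooth_profile(prof$coef, prof$lag, basis_dim)
  prof$r2_smooth <- smooth_profile(prof$r2, prof$lag, basis_dim)
  out <- structure(list(profile = prof, coef_tail = coef_tail,
                        lower_q = lower_q, upper_q = upper_q,
                        reference_day = attr(matrix, "reference_day")),
                   class = "pc_csp_profile")
  if (!relax) return(extract_critical_window(out))
  ladder <- list(c(lower_q, upper_q), c(0.05, 0.95), c(0.1, 0.9),
                 c(0.25, 0.75))
  for (q in ladder) {
    out$lower_q <- q[1]; out$upper_q <- q[2]
    res <- tryCatch(extract_critical_window(out), error = function(e) NULL)
    if (!is.null(res)) {
      res$relaxed <- !identical(q, c(lower_q, upper_q))
      return(res)
    }
  }
  stop("no critical window even at the widest threshold tails (0.25/0.75)")
}

#' Extract the critical window from a sensitivity profile
#'
#' Marks lags whose smoothed coefficient falls in its extreme tail
#' (at or beyond the 2.5% empirical quantile, on the side given by the
#' effect's sign) and whose smoothed R-squared is at or above its 97.5%
#' quantile, then returns the longest run of consecutive marked lags
#' (ties broken towards the reference day).
#'
#' @param x A `pc_csp_profile` (thresholds are (re)computed from its
#'   smoothed profiles).
#' @return `x` with elements `coef_threshold`, `r2_threshold` and `critical`
#'   (list with `open`, `close`) filled in and an `in_window` column added
#'   to the profile.
#' @export
extract_critical_window <- function(x) {
  stopifnot(inherits(x, "pc_csp_profile"))
  prof <- x$profile
  tail_side <- switch(x$coef_tail,
    auto = {
      med <- stats::median(prof$coef_smooth)
      if (med < 0) "lower"
      else if (med > 0) "upper"
      # median exactly zero (e.g. a mostly-flat profile): fall back to the
      # sign of the mean effect
      else if (mean(prof$coef_smooth) < 0) "lower" else "upper"
    },
    x$coef_tail)
  if (tail_side == "lower") {
    coef_thr <- stats::quantile(prof$coef_smooth, x$lower_q, names = FALSE)
    pass_coef <- prof$coef_smooth <= coef_thr
  } else {
    coef_thr <- stats::quantile(prof$coef_smooth, x$upper_q, names = FALSE)
    pass_coef <- prof$coef_smooth >= coef_thr
  }
  r2_thr <- stats::quantile(prof$r2_smooth, x$upper_q, names = FALSE)
  pass <- pass_coef & prof$r2_smooth >= r2_thr
  if (!any(pass))
    stop("no lag passes both thresholds; relax lower_q/upper_q or check ",
         "the profiles")
  if (all(pass))
    stop("every lag passes both thresholds (flat profiles): the quantile ",
         "rule cannot single out a sensitive period")
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$len <- runs$end - runs$start + 1
  # longest run; ties towards the reference day (smaller close lag)
  runs <- runs[order(-runs$len, prof$lag[runs$start]), ]
  best <- runs[1, ]
  critical <- list(open = prof$lag[best$end], close = prof$lag[best$start])
  prof$in_window <- prof$lag >= critical$close & prof$lag <= critical$open
  x$profile <- prof
  x$coef_threshold <- coef_thr
  x$r2_threshold <- r2_thr
  x$tail_side <- tail_side
  x$critical <- critical
  x
}

#' Fit the CSP cue model
#'
#' The CSP cue is the mean temperature over the critical window; the cue
#' model is the simple linear regression of event day on that cue, exactly
#' as for an absolute sliding window, and predicts via
#' [predict_from_cue()].
#'
#' @param phenology A [pheno_series()].
#' @param matrix A `climate_matrix` covering the phenology years.
#' @param window A `pc_csp_profile`, or a list with `open` and `close` lags.
#' @return A `pc_cue_model` (statistic `"mean"`, absolute frame).
#' @export
fit_csp_cue <- function(phenology, matrix, window) {
  if (inherits(window, "pc_csp_profile")) window <- window$critical
  stopifnot(is.list(window), !is.null(window$open), !is.null(window$close))
  matrix <- subset_years(matrix, phenology$year)
  cue <- matrix_window_values(matrix, window$open, window$close, "mean")
  fit <- fit_linear(cue, as.numeric(phenology$event_day))
  new_cue_model(window$open, window$close, "mean", "absolute", fit,
                attr(matrix, "reference_day"), range(phenology$year))
}

#' @export
print.pc_csp_profile <- function(x, ...) {
  cat(sprintf(
    "<pc_csp_profile> %d lags; critical window lags %d..%d (%s coef tail; coef thr %.3f, r2 thr %.3f)\n",
    nrow(x$profile), x$critical$open, x$critical$close, x$tail_side,
    x$coef_threshold, x$r2_threshold))
  invisible(x)
}
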