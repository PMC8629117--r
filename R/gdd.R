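# Three-parameter growing degree-day (thermal-time) model.
#
# Parameters: start day of accumulation t0 (day of year), base temperature
# Tb (degrees C) and cumulative requirement F* (degree-days). From day t0
# onwards every degree by which the daily mean exceeds Tb is summed; the
# event is predicted on the first day the running sum reaches F*. The
# parameters are fitted by minimizing squared prediction error with a
# seeded, bounded simulated-annealing search plus a coordinate-descent
# polish (the objective is a step function of all three parameters, so
# gradient-based optimizers are unusable). Uncertainty comes from a
# year-resampling percentile bootstrap.

GDD_BOUNDS <- list(start_day = c(1, 200), base_temp = c(1, 10),
                   requirement = c(50, 1000))

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

april1_doy <- function(year) ifelse(is_leap(year), 92L, 91L)

#' Predicted event day from degree-day accumulation (single year)
#'
#' @param temps Numeric vector of daily mean temperatures indexed by day of
#'   year (element 1 = 1 January).
#' @param params List or named vector with `start_day` (t0), `base_temp`
#'   (Tb) and `requirement` (F*).
#' @return The day of year on which the cumulative sum of
#'   `max(0, temp - Tb)` from `t0` first reaches F*, or `NA_integer_` if the
#'   requirement is never met within the supplied series (NOT_REACHED).
#' @export
gdd_event_date <- function(temps, params) {
  t0 <- as.integer(round(params[["start_day"]]))
  tb <- params[["base_temp"]]; fstar <- params[["requirement"]]
  if (t0 < 1 || t0 > length(temps))
    stop("start_day ", t0, " outside the supplied temperature series")
  if (anyNA(temps[t0:length(temps)]))
    stop("temperature series has gaps after the start day")
  inc <- pmax(temps[t0:length(temps)] - tb, 0)
  cum <- cumsum(inc)
  hit <- which(cum >= fstar)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(t0 + hit[1] - 1L)
}

# Years x 366 matrix of daily temperatures by day of year. Missing day 366
# in non-leap years is filled with an impossibly cold value so it never
# contributes to accumulation.
climate_doy_matrix <- function(climate, years) {
  stopifnot(inherits(climate, "climate_series"))
  TM <- matrix(-99, nrow = length(years), ncol = 366,
               dimnames = list(years, NULL))
  cyear <- as.integer(format(climate$date, "%Y"))
  doy <- as.integer(format(climate$date, "%j"))
  for (i in seq_along(years)) {
    sel <- cyear == years[i]
    if (!any(sel)) stop("no climate data for year ", years[i])
    ndays <- 365L + is_leap(years[i])
    have <- doy[sel]
    if (!all(seq_len(ndays) %in% have))
      stop("climate data incomplete for year ", years[i])
    TM[i, have] <- climate$temp[sel]
  }
  TM
}

# Row-wise cumulative sums via one long cumsum (the optimizer calls this in
# a tight loop).
row_cumsum <- function(m) {
  v <- matrix(cumsum(as.vector(t(m))), nrow = nrow(m), byrow = TRUE)
  v - c(0, v[-nrow(m), ncol(m)])
}

# Vectorized event-day prediction for all years at once; NOT_REACHED years
# get the end-of-year penalty day.
gdd_predict_doy <- function(TM, par) {
  t0 <- as.integer(round(par[1]))
  inc <- TM - par[2]
  inc[inc < 0] <- 0
  if (t0 > 1) inc[, seq_len(t0 - 1)] <- 0
  cum <- row_cumsum(inc)
  cnt <- rowSums(cum < par[3])
  ev <- cnt + 1L
  not_reached <- ev > ncol(TM)
  ev[not_reached] <- ncol(TM)
  list(doy = ev, not_reached = not_reached)
}

gdd_objective <- function(par, TM, obs_doy, mode) {
  pred <- gdd_predict_doy(TM, par)$doy
  if (mode == "direct") {
    sum((pred - obs_doy)^2)
  } else {
    # residual SS of lm(predicted ~ observed); degenerate (constant
    # predictions) would be rewarded with RSS 0, so it is penalized
    soo <- sum((obs_doy - mean(obs_doy))^2)
    spp <- sum((pred - mean(pred))^2)
    if (spp < 1e-8) return(sum((pred - obs_doy)^2) + 1e6)
    sop <- sum((obs_doy - mean(obs_doy)) * (pred - mean(pred)))
    max(spp - sop^2 / soo, 0)
  }
}

# Bounded simulated annealing with geometric cooling and reflecting
# proposals, followed by a coordinate-descent polish on a shrinking grid.
sa_minimize <- function(fn, lower, upper, start = NULL, maxit = 3000,
                        t0_frac = 0.1, cooling = NULL, step0 = 0.25,
                        step_min = 0.01, polish = TRUE) {
  rng <- upper - lower
  p <- length(lower)
  reflect <- function(x) {
    for (j in seq_len(p)) {
      while (x[j] < lower[j] || x[j] > upper[j]) {
        if (x[j] < lower[j]) x[j] <- 2 * lower[j] - x[j]
        if (x[j] > upper[j]) x[j] <- 2 * upper[j] - x[j]
      }
    }
    x
  }
  cur <- if (is.null(start)) lower + stats::runif(p) * rng else start
  fcur <- fn(cur)
  best <- cur; fbest <- fcur
  temp <- abs(fcur) * t0_frac + 1e-8
  if (is.null(cooling)) cooling <- (1e-4)^(1 / maxit)
  step_decay <- (step_min / step0)^(1 / maxit)
  step <- step0
  for (it in seq_len(maxit)) {
    cand <- reflect(cur + stats::rnorm(p) * step * rng)
    fcand <- fn(cand)
    if (fcand <= fcur || stats::runif(1) < exp(-(fcand - fcur) / temp)) {
      cur <- cand; fcur <- fcand
      if (fcur < fbest) { best <- cur; fbest <- fcur }
    }
    temp <- temp * cooling
    step <- step * step_decay
  }
  if (polish) {
    clamp <- function(x) pmin(pmax(x, lower), upper)
    for (frac in c(0.05, 0.02, 0.005, 0.001)) {
      improved <- TRUE
      guard <- 0L
      while (improved && guard < 200L) {
        improved <- FALSE
        guard <- guard + 1L
        # axis moves plus a few random directions (the objective often has
        # a ridge where parameters compensate each other)
        dirs <- rbind(diag(p), -diag(p),
                      matrix(stats::rnorm(8 * p), ncol = p))
        for (k in seq_len(nrow(dirs))) {
          d <- dirs[k, ] / sqrt(sum(dirs[k, ]^2))
          cand <- clamp(best + frac * d * rng)
          fcand <- fn(cand)
          if (fcand < fbest) { best <- cand; fbest <- fcand; improved <- TRUE }
        }
      }
    }
  }
  list(par = best, value = fbest)
}

#' Fit the growing degree-day model
#'
#' Global stochastic search over the bounded parameter box (simulated
#' annealing with restarts and a local polish), minimizing either the direct
#' sum of squared prediction errors (`objective = "direct"`, default) or the
#' residual sum of squares of a regression of predicted on observed dates
#' (`objective = "regression"`).
#'
#' @param phenology A [pheno_series()].
#' @param climate A [climate_series()] covering every phenology year in full.
#' @param bounds List with elements `start_day`, `base_temp`, `requirement`,
#'   each a length-2 numeric range. Defaults: start day 1-200, base
#'   temperature 1-10 degrees C, requirement 50-1000 degree-days.
#' @param objective `"direct"` or `"regression"` (see Details).
#' @param seed Integer seed for the stochastic search (identical seed,
#'   identical fit).
#' @param control List: `maxit` (SA iterations per restart, default 3000),
#'   `restarts` (default 3), `polish` (default TRUE).
#' @return An object of class `pc_gdd_fit`: list with `params` (named
#'   vector: start_day, base_temp, requirement), `objective_value`,
#'   `objective_mode`, per-year `predicted` (days since 1 April),
#'   `not_reached`, `cue_fit` (a `pc_linfit` of observed on predicted day,
#'   for variance-explained reporting), `bounds`, `years`. Bootstrap
#'   elements are added by [bootstrap_gdd()].
#' @export
fit_gdd <- function(phenology, climate, bounds = GDD_BOUNDS,
                    objective = c("direct", "regression"), seed = NULL,
                    control = list()) {
  objective <- match.arg(objective)
  stopifnot(inherits(phenology, "pheno_series"))
  if (nrow(phenology) < 5) stop("need at least 5 years to fit the GDD model")
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  if (any(lower >= upper)) stop("inverted parameter bounds")
  ctl <- utils::modifyList(list(maxit = 3000, restarts = 3, polish = TRUE),
                           control)
  TM <- climate_doy_matrix(climate, phenology$year)
  obs_doy <- phenology$event_day + april1_doy(phenology$year) - 1L
  fn <- function(par) gdd_objective(par, TM, obs_doy, objective)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(ctl$restarts)) {
    res <- sa_minimize(fn, lower, upper, maxit = ctl$maxit,
                       polish = ctl$polish)
    if (is.null(best) || res$value < best$value) best <- res
  }
  par <- best$par
  names(par) <- c("start_day", "base_temp", "requirement")
  par["start_day"] <- round(par["start_day"])
  pred <- gdd_predict_doy(TM, par)
  pred_days <- pred$doy - april1_doy(phenology$year) + 1L
  cue_fit <- tryCatch(fit_linear(pred_days, as.numeric(phenology$event_day)),
                      error = function(e) NULL)
  structure(list(params = par, objective_value = best$value,
                 objective_mode = objective, predicted = pred_days,
                 not_reached = pred$not_reached, cue_fit = cue_fit,
                 bounds = bounds, years = phenology$year,
                 control = ctl, seed = seed),
            class = "pc_gdd_fit")
}

#' Bootstrap percentile confidence intervals for GDD parameters
#'
#' Resamples years with replacement, refits the model on each replicate
#' (starting the search from the point estimate, with a reduced iteration
#' budget) and takes empirical 2.5/97.5 percentiles per parameter.
#'
#' @param fit A `pc_gdd_fit` from [fit_gdd()].
#' @param phenology,climate The data used to fit.
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param boot_maxit SA iterations per replicate (default 400).
#' @return `fit`, with `boot_params` (reps x 3 matrix), `ci_low`, `ci_high`
#'   added. If a point estimate falls outside its interval (possible under
#'   multimodality) a warning is issued.
#' @export
bootstrap_gdd <- function(fit, phenology, climate, reps = 1000, seed = NULL,
                          level = 0.95, boot_maxit = 400) {
  stopifnot(inherits(fit, "pc_gdd_fit"))
  if (reps < 2) stop("need at least 2 bootstrap replicates")
  lower <- vapply(fit$bounds, `[`, numeric(1), 1)
  upper <- vapply(fit$bounds, `[`, numeric(1), 2)
  TM <- climate_doy_matrix(climate, phenology$year)
  obs_doy <- phenology$event_day + april1_doy(phenology$year) - 1L
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(phenology)
  bp <- matrix(NA_real_, nrow = reps, ncol = 3,
               dimnames = list(NULL, names(fit$params)))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    fn <- function(par) gdd_objective(par, TM[idx, , drop = FALSE],
                                      obs_doy[idx], fit$objective_mode)
    res <- sa_minimize(fn, lower, upper, start = unname(fit$params),
                       maxit = boot_maxit, polish = TRUE)
    bp[r, ] <- res$par
  }
  bp[, "start_day"] <- round(bp[, "start_day"])
  a <- (1 - level) / 2
  fit$boot_params <- bp
  fit$ci_low <- apply(bp, 2, stats::quantile, probs = a, names = FALSE)
  fit$ci_high <- apply(bp, 2, stats::quantile, probs = 1 - a, names = FALSE)
  outside <- fit$params < fit$ci_low | fit$params > fit$ci_high
  if (any(outside))
    warning("point estimate outside its bootstrap interval for: ",
            paste(names(fit$params)[outside], collapse = ", "),
            " (possible multimodality)")
  fit
}

#' Predict event days from a fitted GDD model
#'
#' Point predictions use the point parameter estimates. Prediction intervals
#' are the min/max envelope of predicted dates over the 8 corner
#' combinations of the per-parameter bootstrap confidence bounds.
#'
#' @param fit A `pc_gdd_fit` with bootstrap intervals
#'   (see [bootstrap_gdd()]).
#' @param climate A [climate_series()] covering the test years.
#' @param years Integer vector of test years.
#' @return A `pc_predictions` data frame (year, predicted, pi_low, pi_high,
#'   not_reached, not_reached_corners), dates in days since 1 April.
#' @export
predict_gdd <- function(fit, climate, years) {
  stopifnot(inherits(fit, "pc_gdd_fit"))
  if (is.null(fit$ci_low))
    stop("fit has no bootstrap intervals; run bootstrap_gdd() first")
  years <- as.integer(years)
  TM <- climate_doy_matrix(climate, years)
  a1 <- april1_doy(years)
  point <- gdd_predict_doy(TM, unname(fit$params))
  corners <- as.matrix(expand.grid(
    start_day = c(fit$ci_low[1], fit$ci_high[1]),
    base_temp = c(fit$ci_low[2], fit$ci_high[2]),
    requirement = c(fit$ci_low[3], fit$ci_high[3])))
  lo <- rep(Inf, length(years)); hi <- rep(-Inf, length(years))
  nr_corners <- rep(0L, length(years))
  for (k in seq_len(nrow(corners))) {
    p <- gdd_predict_doy(TM, corners[k, ])
    lo <- pmin(lo, p$doy); hi <- pmax(hi, p$doy)
    nr_corners <- nr_corners + p$not_reached
  }
  structure(data.frame(
    year = years,
    predicted = point$doy - a1 + 1, pi_low = lo - a1 + 1, pi_high = hi - a1 + 1,
    not_reached = point$not_reached, not_reached_corners = nr_corners),
    class = c("pc_predictions", "data.frame"))
}

#' @export
print.pc_gdd_fit <- function(x, ...) {
  cat(sprintf(
    "<pc_gdd_fit> t0=%d  Tb=%.2f degC  F*=%.1f degC-days  SSQ(%s)=%.1f\n",
    as.integer(x$params["start_day"]), x$params["base_temp"],
    x$params["requirement"], x$objective_mode, x$objective_value))
  if (!is.null(x$ci_low)) {
    ci <- sprintf("  %s: [%.1f, %.1f]", names(x$params), x$ci_low, x$ci_high)
    cat("  bootstrap 95% CIs:\n", paste(ci, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}
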