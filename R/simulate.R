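# Synthetic climate and phenology with known ground truth.
#
# The climate generator produces daily mean temperatures with a sinusoidal
# seasonal cycle, an optional linear warming trend and AR(1) daily noise
# parameterized by its stationary standard deviation (so noise_sd keeps its
# meaning whatever the autocorrelation). The phenology generator plants one
# of the three cue mechanisms the identification methods assume -- a
# fixed-window aggregate, a distributed (functional) coefficient over lags,
# or degree-day accumulation -- and adds Gaussian year-to-year noise, so
# every method can be tested by parameter recovery.

#' Simulate a daily climate series
#'
#' `T(d) = annual_mean + warming_trend * (year(d) - first_year) +
#'  seasonal_amplitude * cos(2*pi*(doy(d) - seasonal_phase)/365.25) + e(d)`
#' with `e` a stationary AR(1) process of standard deviation `noise_sd` and
#' lag-1 autocorrelation `ar1_rho`.
#'
#' @param years Integer vector of event years the series must support; the
#'   series runs from 1 January of `min(years) - pad_years` through
#'   31 December of `max(years)`.
#' @param annual_mean Mean temperature, degrees C (default 9.5).
#' @param seasonal_amplitude Half-range of the seasonal cycle, degrees C
#'   (default 6.5).
#' @param seasonal_phase Day of year of the seasonal maximum (default 200,
#'   mid-July).
#' @param warming_trend Linear trend, degrees C per year (default 0).
#' @param ar1_rho Lag-1 autocorrelation of daily noise, in [0, 1)
#'   (default 0.7).
#' @param noise_sd Stationary standard deviation of daily noise, degrees C
#'   (default 2.5).
#' @param seed Integer seed (same seed, identical series).
#' @param pad_years Extra lead years of coverage (default 1, enough for a
#'   365-day look-back from any reference or event day).
#' @return A [climate_series()].
#' @export
simulate_climate <- function(years, annual_mean = 9.5, seasonal_amplitude = 6.5,
                             seasonal_phase = 200, warming_trend = 0,
                             ar1_rho = 0.7, noise_sd = 2.5, seed = NULL,
                             pad_years = 1) {
  stopifnot(noise_sd >= 0, abs(ar1_rho) < 1)
  y0 <- min(years)
  dates <- seq(as.Date(sprintf("%d-01-01", y0 - pad_years)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  dyear <- as.integer(format(dates, "%Y"))
  det <- annual_mean + warming_trend * (dyear - y0) +
    seasonal_amplitude * cos(2 * pi * (doy - seasonal_phase) / 365.25)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dates)
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1_rho^2)
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, noise_sd)
    z <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) e[i] <- ar1_rho * e[i - 1] + z[i - 1]
  } else e <- numeric(n)
  climate_series(dates, det + e)
}

#' Simulate annual event days from a planted temperature cue
#'
#' @param climate A [climate_series()].
#' @param years Event years to generate.
#' @param mechanism `"window"` (aggregate over a fixed lag window),
#'   `"distributed"` (linear functional of the whole lag profile) or
#'   `"gdd"` (degree-day accumulation via [gdd_event_date()]).
#' @param truth Mechanism-specific ground truth:
#'   * window: `list(window = list(open, close, statistic, frame = "absolute"),
#'     intercept, slope)` (frame `"relative"` anchors the window to the event
#'     day itself and solves the implied fixed point per year);
#'   * distributed: `list(intercept, beta, lags)` with `beta` the coefficient
#'     (days per degree C per day) at each lag;
#'   * gdd: `list(start_day, base_temp, requirement)`.
#' @param noise_sd Standard deviation of additive Gaussian year noise, days
#'   (default 2).
#' @param seed Integer seed.
#' @param reference_day Anchor for absolute lags (default `"05-20"`).
#' @param bounds Validation bounds passed to [pheno_series()].
#' @return A list with `phenology` (a [pheno_series()], event days rounded
#'   to whole days), `truth` (the truth record, with the noise-free means
#'   attached as `latent_mean`).
#' @export
simulate_phenology <- function(climate, years,
                               mechanism = c("window", "distributed", "gdd"),
                               truth, noise_sd = 2, seed = NULL,
                               reference_day = "05-20", bounds = c(1, 120)) {
  mechanism <- match.arg(mechanism)
  years <- sort(as.integer(years))
  if (!is.null(seed)) set.seed(seed)
  if (mechanism == "window") {
    w <- truth$window
    frame <- if (is.null(w$frame)) "absolute" else w$frame
    if (frame == "absolute") {
      M <- build_climate_matrix(climate, years, reference_day,
                                lags = 0:max(365, w$open))
      cue <- matrix_window_values(M, w$open, w$close, w$statistic)
      latent <- truth$intercept + truth$slope * cue
    } else {
      # Event-anchored cue: the event day must satisfy
      # d = intercept + slope * aggregate(T over the window before day d).
      # Because the cue is piecewise constant in whole days, the fixed
      # point is found by exhaustive search over candidate days rather
      # than iteration (which can oscillate between adjacent days).
      latent <- vapply(years, function(y) {
        cand <- seq(bounds[1], bounds[2])
        origin <- as.Date(sprintf("%d-%s", y, pc_day_origin()))
        g <- vapply(cand, function(d) {
          idx <- match((origin + d - 1) - seq(w$open, w$close), climate$date)
          if (anyNA(idx))
            stop("climate coverage insufficient for relative window in year ",
                 y)
          truth$intercept +
            truth$slope * window_aggregate(climate$temp[idx], w$statistic)
        }, numeric(1))
        gap <- abs(g - cand)
        if (min(gap) > 1)
          stop("no self-consistent event day (within one day) for the ",
               "relative window in year ", y)
        cand[which.min(gap)]
      }, numeric(1))
    }
  } else if (mechanism == "distributed") {
    M <- build_climate_matrix(climate, years, reference_day,
                              lags = as.integer(truth$lags))
    latent <- as.numeric(truth$intercept + unclass(M) %*% truth$beta)
  } else {
    TM <- climate_doy_matrix(climate, years)
    p <- gdd_predict_doy(TM, c(truth$start_day, truth$base_temp,
                               truth$requirement))
    if (any(p$not_reached))
      stop("degree-day requirement never reached in year ",
           years[which(p$not_reached)[1]])
    latent <- p$doy - april1_doy(years) + 1
  }
  ev <- round(latent + stats::rnorm(length(years), 0, noise_sd))
  truth$latent_mean <- latent
  truth$mechanism <- mechanism
  truth$noise_sd <- noise_sd
  truth$reference_day <- reference_day
  list(phenology = pheno_series(years, ev, bounds = bounds), truth = truth)
}

#' Bundled demonstration scenario
#'
#' Fifty-five years of daily temperature (UK-like seasonal cycle, AR(1)
#' daily noise, 0.03 degrees C per year warming) and a planted mean-
#' temperature cue over lag days 81..14 before 20 May with slope -6 days
#' per degree C and 2 days of annual noise.
#'
#' @return A scenario list accepted by [simulate_scenario()].
#' @export
default_scenario <- function() {
  list(
    years = 1961:2015,
    reference_day = "05-20",
    climate = list(annual_mean = 9.5, seasonal_amplitude = 6.5,
                   seasonal_phase = 200, warming_trend = 0.03,
                   ar1_rho = 0.7, noise_sd = 2.5),
    phenology = list(
      mechanism = "window",
      truth = list(window = list(open = 81, close = 14, statistic = "mean",
                                 frame = "absolute"),
                   intercept = 76, slope = -6),
      noise_sd = 2))
}

#' Run a simulation scenario
#'
#' @param scenario A scenario list (see [default_scenario()] for the
#'   structure; scenarios are YAML-serializable).
#' @param seed Integer seed controlling both climate and phenology noise.
#' @return List with `climate`, `phenology`, `truth`.
#' @export
simulate_scenario <- function(scenario = default_scenario(), seed = 1) {
  years <- scenario$years
  if (!is.null(scenario$years_range))
    years <- scenario$years_range[1]:scenario$years_range[2]
  cl <- do.call(simulate_climate,
                c(list(years = years, seed = seed), scenario$climate))
  ph <- simulate_phenology(
    cl, years, mechanism = scenario$phenology$mechanism,
    truth = scenario$phenology$truth,
    noise_sd = scenario$phenology$noise_sd,
    seed = seed + 1L,
    reference_day = scenario$reference_day %||% "05-20")
  list(climate = cl, phenology = ph$phenology, truth = ph$truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
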