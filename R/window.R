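# Exhaustive sliding-time-window search.
#
# Candidate windows are spans of consecutive lag days [close, open] (lags
# counted backwards from the anchor; open >= close). Within each window the
# daily mean temperatures are collapsed to one of four aggregate statistics
# and the aggregate is regressed against annual mean event day. Candidates
# are ranked by AICc against an intercept-only baseline.
#
# The search is vectorized: window sums come from cumulative sums across
# lags, the within-window temperature slope from a second weighted cumsum,
# and running pmin/pmax give min/max aggregates. The per-candidate OLS is
# the closed form of fit_linear() applied column-wise, so the vectorized
# path and the naive loop agree to floating-point summation order (tested).

WINDOW_STATISTICS <- c("mean", "min", "max", "slope")

#' Aggregate daily temperatures within a window
#'
#' @param temps Numeric vector of daily mean temperatures ordered oldest to
#'   newest (i.e. from the window's open day towards its close day).
#' @param statistic One of `"mean"`, `"min"`, `"max"`, `"slope"`. The slope
#'   is the OLS gradient of temperature against day-in-window (degrees C per
#'   day; positive = warming towards the event) and requires at least two
#'   days.
#' @return A single numeric value.
#' @export
window_aggregate <- function(temps, statistic = WINDOW_STATISTICS) {
  statistic <- match.arg(statistic)
  if (length(temps) < 1) stop("empty window")
  switch(statistic,
    mean = mean(temps),
    min = min(temps),
    max = max(temps),
    slope = {
      m <- length(temps)
      if (m < 2) stop("slope aggregate undefined for a 1-day window")
      tt <- seq_len(m)
      sum((tt - mean(tt)) * (temps - mean(temps))) / sum((tt - mean(tt))^2)
    })
}

# Aggregate one window for every row of a climate matrix.
matrix_window_values <- function(matrix, open, close, statistic) {
  lags <- attr(matrix, "lags")
  need <- seq(open, close) # descending lag = oldest -> newest
  idx <- match(need, lags)
  if (anyNA(idx))
    stop("window lags ", close, "..", open, " not covered by climate matrix")
  sub <- matrix[, idx, drop = FALSE]
  unname(apply(sub, 1, window_aggregate, statistic = statistic))
}

# Enumerate all candidate windows over contiguous lags and compute the
# aggregate matrix (years x candidates) for one statistic.
window_aggregate_matrix <- function(X, lags, max_duration, statistic) {
  m <- length(lags)
  stopifnot(ncol(X) == m, all(diff(lags) == 1L))
  maxd <- min(max_duration, m)
  # candidate index pairs (position of close, position of open)
  close_idx <- unlist(lapply(seq_len(m), function(jc)
    rep(jc, min(maxd, m - jc + 1))))
  open_idx <- unlist(lapply(seq_len(m), function(jc)
    jc:(jc + min(maxd, m - jc + 1) - 1)))
  dur <- open_idx - close_idx + 1
  if (statistic == "slope") {
    keep <- dur >= 2
    close_idx <- close_idx[keep]; open_idx <- open_idx[keep]; dur <- dur[keep]
  }
  n <- nrow(X)
  if (statistic %in% c("mean", "slope")) {
    CS <- cbind(0, t(apply(X, 1, cumsum)))
    S <- CS[, open_idx + 1, drop = FALSE] - CS[, close_idx, drop = FALSE]
    if (statistic == "mean") {
      A <- sweep(S, 2, dur, "/")
    } else {
      P <- sweep(X, 2, seq_len(m), "*")
      CSP <- cbind(0, t(apply(P, 1, cumsum)))
      SP <- CSP[, open_idx + 1, drop = FALSE] - CSP[, close_idx, drop = FALSE]
      # day-in-window index j = open_pos + 1 - p (oldest day j = 1)
      Sjx <- sweep(S, 2, open_idx + 1, "*") - SP
      tbar <- (dur + 1) / 2
      sxx_t <- dur * (dur^2 - 1) / 12
      A <- (Sjx - sweep(S, 2, tbar, "*")) / rep(sxx_t, each = n)
    }
  } else {
    fun <- if (statistic == "min") pmin else pmax
    A <- matrix(NA_real_, nrow = n, ncol = length(dur))
    col <- 0L
    for (jc in seq_len(m)) {
      upper <- jc + min(maxd, m - jc + 1) - 1L
      cur <- X[, jc]
      A[, col + 1L] <- cur
      if (upper > jc) {
        for (jo in (jc + 1L):upper) {
          cur <- fun(cur, X[, jo])
          A[, col + (jo - jc + 1L)] <- cur
        }
      }
      col <- col + (upper - jc + 1L)
    }
  }
  list(open = lags[open_idx], close = lags[close_idx], duration = dur, A = A)
}

# Column-wise closed-form OLS + AICc for an aggregate matrix.
score_candidates <- function(A, y) {
  n <- length(y)
  ym <- mean(y); yc <- y - ym
  syy <- sum(yc^2)
  am <- colMeans(A)
  sxy <- as.vector(crossprod(A, yc))
  sxx <- colSums(A^2) - n * am^2
  degenerate <- sxx <= .Machine$double.eps * n * pmax(1, am^2)
  slope <- ifelse(degenerate, NA_real_, sxy / sxx)
  rss <- pmax(syy - slope * sxy, 0)
  sigma2 <- rss / (n - 2)
  r2 <- if (syy > 0) 1 - rss / syy else rep(0, length(slope))
  aic <- aicc_from_rss(rss, n, k = 3)
  aic[degenerate] <- Inf
  data.frame(
    intercept = ym - slope * am, slope = slope,
    slope_se = sqrt(sigma2 / sxx), r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    aicc = aic)
}

search_core <- function(X, y, lags, statistics, max_duration) {
  pieces <- lapply(statistics, function(s) {
    agg <- window_aggregate_matrix(X, lags, max_duration, s)
    cbind(data.frame(open = agg$open, close = agg$close,
                     duration = agg$duration, statistic = s),
          score_candidates(agg$A, y))
  })
  res <- do.call(rbind, pieces)
  baseline <- aicc(y)
  res$delta_aicc <- res$aicc - baseline
  # rank: AICc ascending with ties (to 1e-8) broken towards shorter, more
  # recent windows; statistic order as supplied for full determinism
  key <- round(res$aicc * 1e8)
  res <- res[order(key, res$duration, res$close,
                   match(res$statistic, statistics)), ]
  rownames(res) <- NULL
  list(results = res, baseline_aicc = baseline)
}

new_cue_model <- function(open, close, statistic, frame, fit, reference_day,
                          training_years) {
  structure(list(
    window = list(open = open, close = close, statistic = statistic,
                  frame = frame),
    fit = fit, reference_day = reference_day,
    training_years = training_years), class = "pc_cue_model")
}

#' Exhaustive absolute sliding-window search
#'
#' Scores every window of consecutive lag days before the calendar reference
#' day (all positions and durations up to `max_duration`) under each
#' aggregate statistic, ranks candidates by AICc and compares the best
#' against an intercept-only baseline.
#'
#' @param phenology A [pheno_series()].
#' @param matrix A `climate_matrix` built with [build_climate_matrix()]
#'   covering (at least) the phenology years.
#' @param statistics Subset of `c("mean", "min", "max", "slope")`.
#' @param max_duration Maximum window length in days (default 365).
#' @return An object of class `pc_window_scan`: list with `results` (ranked
#'   candidate table: open, close, duration, statistic, intercept, slope,
#'   slope_se, r2, r2_adj, aicc, delta_aicc), `baseline_aicc`, `best`
#'   (a `pc_cue_model` for the top-ranked window), `frame`, `years`.
#' @export
search_absolute <- function(phenology, matrix,
                            statistics = WINDOW_STATISTICS,
                            max_duration = 365) {
  stopifnot(inherits(phenology, "pheno_series"),
            inherits(matrix, "climate_matrix"))
  statistics <- match.arg(statistics, WINDOW_STATISTICS, several.ok = TRUE)
  if (!all(phenology$year %in% attr(matrix, "years")))
    stop("climate matrix does not cover all phenology years")
  if (nrow(phenology) < 4) stop("need at least 4 years for the window search")
  matrix <- subset_years(matrix, phenology$year)
  sc <- search_core(unclass(matrix)[, , drop = FALSE],
                    as.numeric(phenology$event_day),
                    attr(matrix, "lags"), statistics, max_duration)
  top <- sc$results[1, ]
  fit <- fit_linear(matrix_window_values(matrix, top$open, top$close,
                                         top$statistic),
                    as.numeric(phenology$event_day))
  best <- new_cue_model(top$open, top$close, top$statistic, "absolute", fit,
                        attr(matrix, "reference_day"), range(phenology$year))
  structure(list(results = sc$results, baseline_aicc = sc$baseline_aicc,
                 best = best, frame = "absolute",
                 reference_day = attr(matrix, "reference_day"),
                 statistics = statistics, years = phenology$year),
            class = "pc_window_scan")
}

#' Exhaustive relative (event-anchored) sliding-window search
#'
#' As [search_absolute()], but windows are counted in days before each
#' year's observed event date, so the same window covers different calendar
#' days in different years. Because the cue is defined by the event itself,
#' relative cue models cannot be used for prediction.
#'
#' @param phenology A [pheno_series()].
#' @param climate A [climate_series()] covering at least 365 days before
#'   each year's event date.
#' @param statistics,max_duration As in [search_absolute()].
#' @param lags Lags before the event to consider (default `1:365`).
#' @return A `pc_window_scan` with `frame = "relative"`.
#' @export
search_relative <- function(phenology, climate,
                            statistics = WINDOW_STATISTICS,
                            max_duration = 365, lags = 1:365) {
  stopifnot(inherits(phenology, "pheno_series"))
  if (nrow(phenology) < 4) stop("need at least 4 years for the window search")
  M <- build_relative_matrix(climate, phenology, lags = lags)
  sc <- search_core(unclass(M)[, , drop = FALSE],
                    as.numeric(phenology$event_day),
                    attr(M, "lags"), statistics, max_duration)
  top <- sc$results[1, ]
  fit <- fit_linear(matrix_window_values(M, top$open, top$close, top$statistic),
                    as.numeric(phenology$event_day))
  best <- new_cue_model(top$open, top$close, top$statistic, "relative", fit,
                        "event", range(phenology$year))
  structure(list(results = sc$results, baseline_aicc = sc$baseline_aicc,
                 best = best, frame = "relative", reference_day = "event",
                 statistics = statistics, years = phenology$year),
            class = "pc_window_scan")
}

#' Predict event days from a fitted cue model
#'
#' Aggregates temperatures over the model's fixed window for each test year,
#' applies the fitted line and attaches 95% prediction intervals. Only
#' absolute-frame models can predict: a relative window is anchored to the
#' event date, which is unknown before the event has happened.
#'
#' @param model A `pc_cue_model` (e.g. `scan$best`).
#' @param matrix A `climate_matrix` for the test years (same reference day).
#' @param level Prediction-interval coverage, default 0.95.
#' @return A data frame (class `pc_predictions`) with columns `year`, `cue`,
#'   `predicted`, `pi_low`, `pi_high`.
#' @export
predict_from_cue <- function(model, matrix, level = 0.95) {
  stopifnot(inherits(model, "pc_cue_model"))
  if (model$window$frame != "absolute")
    stop("relative-window cue models cannot predict: the window is anchored ",
         "to the event date, so identifying the cue requires the event to ",
         "have already occurred")
  cue <- matrix_window_values(matrix, model$window$open, model$window$close,
                              model$window$statistic)
  pi <- prediction_interval(model$fit, cue, level = level)
  structure(data.frame(year = attr(matrix, "years"), cue = cue, pi),
            class = c("pc_predictions", "data.frame"))
}

#' @export
print.pc_window_scan <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<pc_window_scan> %s frame, %d candidates, %d years\n", x$frame,
    nrow(x$results), length(x$years)))
  cat(sprintf(
    "  best: %s over lags %d..%d  slope=%.3f  adj R2=%.3f  dAICc=%.2f\n",
    b$window$statistic, b$window$open, b$window$close, b$fit$slope,
    b$fit$r2_adj, x$results$delta_aicc[1]))
  invisible(x)
}

#' @export
print.pc_cue_model <- function(x, ...) {
  cat(sprintf(
    "<pc_cue_model> %s %s over lags %d..%d before %s; intercept=%.2f slope=%.2f (SE %.2f) adj R2=%.2f\n",
    x$window$frame, x$window$statistic, x$window$open, x$window$close,
    x$reference_day, x$fit$intercept, x$fit$slope, x$fit$slope_se,
    x$fit$r2_adj))
  invisible(x)
}
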