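# Shared fixtures and independent oracles, all built in code.

# Deterministic toy climate: temperature is an invertible function of the
# date so matrix entries can be predicted in closed form.
toy_climate_linear <- function(from, to) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  climate_series(dates, as.numeric(dates - as.Date("1970-01-01")) / 100)
}

# Small random climate matrix with the climate_matrix structure (no real
# calendar behind it), for unit tests of the search machinery.
toy_matrix <- function(n_years, lags, seed, first_year = 2001L) {
  set.seed(seed)
  years <- first_year + seq_len(n_years) - 1L
  M <- matrix(stats::rnorm(n_years * length(lags), mean = 8, sd = 2),
              nrow = n_years, dimnames = list(years, paste0("d", lags)))
  structure(M, class = c("climate_matrix", "matrix"), years = years,
            lags = as.integer(lags), reference_day = "05-20")
}

toy_pheno <- function(years, event_day) pheno_series(years, event_day)

# Brute-force sliding-window oracle: double loop over every window and
# statistic, one OLS + AICc per candidate, same tie-break rule.
brute_force_search <- function(M, y, statistics, max_duration = 365) {
  lags <- attr(M, "lags")
  rows <- list()
  for (s in statistics) {
    for (close in lags) {
      for (open in lags[lags >= close]) {
        dur <- open - close + 1
        if (dur > max_duration) next
        if (s == "slope" && dur < 2) next
        cue <- apply(unclass(M)[, match(seq(open, close), lags), drop = FALSE],
                     1, window_aggregate, statistic = s)
        f <- fit_linear(cue, y)
        rows[[length(rows) + 1]] <- data.frame(
          open = open, close = close, duration = dur, statistic = s,
          intercept = f$intercept, slope = f$slope, slope_se = f$slope_se,
          r2 = f$r2, r2_adj = f$r2_adj, aicc = aicc(f))
      }
    }
  }
  res <- do.call(rbind, rows)
  res$delta_aicc <- res$aicc - aicc(y)
  key <- round(res$aicc * 1e8)
  res <- res[order(key, res$duration, res$close,
                   match(res$statistic, statistics)), ]
  rownames(res) <- NULL
  res
}

# Naive day-by-day degree-day accumulation oracle.
naive_gdd <- function(temps, t0, tb, fstar) {
  acc <- 0
  for (d in t0:length(temps)) {
    acc <- acc + max(0, temps[d] - tb)
    if (acc >= fstar) return(d)
  }
  NA_integer_
}

# Type-7 empirical quantile computed from first principles (independent of
# stats::quantile).
manual_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# Standard planted-window simulation: n years, mean-temperature cue over
# lags 81..14 before 20 May, slope -6 days/degC.
planted_window_sim <- function(seed, n_years = 50, noise_sd = 2,
                               warming = 0) {
  years <- 1960 + seq_len(n_years)
  cl <- simulate_climate(years, warming_trend = warming, seed = seed)
  sim <- simulate_phenology(
    cl, years, mechanism = "window",
    truth = list(window = list(open = 81, close = 14, statistic = "mean"),
                 intercept = 76, slope = -6),
    noise_sd = noise_sd, seed = seed + 5000L)
  list(climate = cl, phenology = sim$phenology, truth = sim$truth)
}
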