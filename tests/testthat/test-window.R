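test_that("window aggregates are computed on oldest-to-newest daily values", {
  expect_equal(window_aggregate(c(10, 12, 14), "mean"), 12)
  expect_equal(window_aggregate(c(10, 12, 14), "min"), 10)
  expect_equal(window_aggregate(c(10, 12, 14), "max"), 14)
  expect_equal(window_aggregate(c(10, 12, 14), "slope"), 2) # warming, degC/day
  expect_equal(window_aggregate(rep(5, 8), "slope"), 0)
  expect_error(window_aggregate(7, "slope"), "1-day window")
})

test_that("the vectorized search equals the brute-force oracle on a toy", {
  M <- toy_matrix(6, 0:9, seed = 21)
  y <- c(30, 26, 34, 28, 25, 31)
  ph <- toy_pheno(attr(M, "years"), y)
  scan <- search_absolute(ph, M)
  oracle <- brute_force_search(M, y, WINDOW_STATISTICS)
  expect_equal(nrow(scan$results), nrow(oracle))
  expect_equal(scan$results$open, oracle$open)
  expect_equal(scan$results$close, oracle$close)
  expect_equal(scan$results$statistic, oracle$statistic)
  expect_equal(scan$results$aicc, oracle$aicc, tolerance = 1e-8)
  expect_equal(scan$results$slope, oracle$slope, tolerance = 1e-8)
  expect_equal(scan$results$r2_adj, oracle$r2_adj, tolerance = 1e-8)
  expect_equal(scan$baseline_aicc, aicc(y))
})

test_that("candidate counts follow the window-combinatorics formula", {
  M <- toy_matrix(6, 0:9, seed = 22)
  ph <- toy_pheno(attr(M, "years"), c(30, 26, 34, 28, 25, 31))
  D <- 10
  scan <- search_absolute(ph, M)
  # 4 statistics x D(D+1)/2 windows, minus the D one-day slope windows
  expect_equal(nrow(scan$results), 4 * D * (D + 1) / 2 - D)
  scan2 <- search_absolute(ph, M, statistics = "mean", max_duration = 4)
  expect_equal(nrow(scan2$results), sum(D - seq_len(4) + 1))
})

test_that("one-day windows make mean, min and max coincide", {
  M <- toy_matrix(8, 0:5, seed = 23)
  ph <- toy_pheno(attr(M, "years"), round(stats::runif(8, 20, 40)))
  scan <- search_absolute(ph, M)
  res <- scan$results[scan$results$duration == 1, ]
  byw <- split(res, paste(res$open, res$close))
  for (w in byw) {
    expect_equal(w$slope[w$statistic == "mean"],
                 w$slope[w$statistic == "min"], tolerance = 1e-12)
    expect_equal(w$aicc[w$statistic == "mean"],
                 w$aicc[w$statistic == "max"], tolerance = 1e-12)
  }
})

test_that("a noise-free planted window is recovered essentially exactly", {
  years <- 1981:2010
  cl <- simulate_climate(years, seed = 301)
  sim <- simulate_phenology(
    cl, years, mechanism = "window",
    truth = list(window = list(open = 60, close = 30, statistic = "mean"),
                 intercept = 76, slope = -6),
    noise_sd = 0, seed = 302)
  M <- build_climate_matrix(cl, years)
  scan <- search_absolute(sim$phenology, M, statistics = "mean")
  top <- scan$results[1, ]
  expect_gt(top$r2, 0.995) # whole-day rounding is the only noise
  # top window overlaps the planted one (neighbours are correlated)
  expect_true(top$open >= 30 && top$close <= 60)
})

test_that("relative windows reproduce a self-consistent event-anchored cue", {
  years <- 1981:2006
  cl <- simulate_climate(years, seed = 401)
  sim <- simulate_phenology(
    cl, years, mechanism = "window",
    truth = list(window = list(open = 30, close = 1, statistic = "mean",
                               frame = "relative"),
                 intercept = 55, slope = -4),
    noise_sd = 0, seed = 402)
  scan <- search_relative(sim$phenology, cl, statistics = "mean",
                          max_duration = 60, lags = 1:60)
  row <- scan$results[scan$results$open == 30 & scan$results$close == 1, ]
  expect_gt(row$r2, 0.95) # exact up to whole-day event resolution
})

test_that("relative search refuses a single-year series", {
  cl <- simulate_climate(1990, seed = 51)
  ph <- pheno_series(1990, 30)
  expect_error(search_relative(ph, cl), "at least 4 years")
})

test_that("cue-model predictions follow the fitted line with valid intervals", {
  sim <- planted_window_sim(seed = 61, n_years = 30)
  M <- build_climate_matrix(sim$climate, sim$phenology$year)
  scan <- search_absolute(sim$phenology, M, statistics = "mean")
  pred <- predict_from_cue(scan$best, M)
  # prediction on a training year equals that year's fitted value
  expect_equal(pred$predicted, scan$best$fit$fitted, tolerance = 1e-10)
  expect_true(all(pred$pi_low <= pred$predicted &
                  pred$predicted <= pred$pi_high))
  # hand arithmetic: slope -6, intercept 160, window mean 10 -> 100
  m <- scan$best
  m$fit$intercept <- 160; m$fit$slope <- -6
  Mc <- M
  Mc[] <- 10
  p10 <- predict_from_cue(m, Mc)
  expect_equal(p10$predicted, rep(100, nrow(Mc)))
})

test_that("relative-frame cue models refuse to predict", {
  years <- 1981:2000
  cl <- simulate_climate(years, seed = 71)
  sim <- simulate_phenology(
    cl, years, mechanism = "window",
    truth = list(window = list(open = 40, close = 10, statistic = "mean"),
                 intercept = 76, slope = -6),
    noise_sd = 2, seed = 72)
  # build a relative scan on the same data
  scan <- search_relative(sim$phenology, cl, statistics = "mean",
                          max_duration = 30, lags = 1:50)
  M <- build_climate_matrix(cl, years)
  expect_error(predict_from_cue(scan$best, M), "relative-window")
})

test_that("tied AICc candidates prefer shorter, more recent windows", {
  # two identical lag columns create exact ties between 1-day windows
  M <- toy_matrix(8, 0:3, seed = 81)
  X <- unclass(M)
  X[, 3] <- X[, 2] # lags 1 and 2 identical
  M2 <- structure(X, class = class(M), years = attr(M, "years"),
                  lags = attr(M, "lags"), reference_day = "05-20")
  y <- round(40 - 2 * X[, 2])
  ph <- toy_pheno(attr(M, "years"), y)
  scan <- search_absolute(ph, M2, statistics = "mean")
  ties <- scan$results[scan$results$duration == 1 &
                       scan$results$close %in% c(1, 2), ]
  expect_lt(which(ties$close == 1)[1], which(ties$close == 2)[1])
})
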