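make_matrix <- function(X, lags, years) {
  structure(X, class = c("climate_matrix", "matrix"), years = years,
            lags = as.integer(lags), reference_day = "05-20",
            dimnames = list(years, paste0("d", lags)))
}

test_that("daily regressions return one (coef, r2) pair per lag", {
  sim <- planted_window_sim(seed = 101, n_years = 30)
  M <- build_climate_matrix(sim$climate, sim$phenology$year)
  dr <- daily_regressions(sim$phenology, M)
  expect_equal(nrow(dr), 365)
  expect_equal(dr$lag, 0:364)
  # profile with reference day dropped has 364 lags
  prof <- csp_profile(sim$phenology, M, relax = TRUE)
  expect_equal(nrow(prof$profile), 364)
  expect_equal(min(prof$profile$lag), 1)
})

test_that("identical temperature columns give identical daily regressions", {
  M <- toy_matrix(12, 0:9, seed = 102)
  X <- unclass(M)
  X[, 8] <- X[, 3]
  M2 <- make_matrix(X, 0:9, attr(M, "years"))
  ph <- toy_pheno(attr(M, "years"), round(35 - X[, 3] + stats::rnorm(12)))
  dr <- daily_regressions(ph, M2)
  expect_equal(dr$coef[dr$lag == 7], dr$coef[dr$lag == 2])
  expect_equal(dr$r2[dr$lag == 7], dr$r2[dr$lag == 2])
})

test_that("a degenerate (constant) lag is recorded as zero with a warning", {
  M <- toy_matrix(10, 0:5, seed = 103)
  X <- unclass(M)
  X[, 2] <- 4
  M2 <- make_matrix(X, 0:5, attr(M, "years"))
  ph <- toy_pheno(attr(M, "years"), round(stats::runif(10, 20, 40)))
  expect_warning(dr <- daily_regressions(ph, M2), "constant temperature")
  expect_equal(dr$coef[dr$lag == 1], 0)
  expect_equal(dr$r2[dr$lag == 1], 0)
})

test_that("phenology unrelated to climate yields a flat r2 profile", {
  set.seed(104)
  years <- 1961:2010
  cl <- simulate_climate(years, seed = 104)
  ph <- pheno_series(years, round(stats::rnorm(50, 30, 5)))
  M <- build_climate_matrix(cl, years)
  dr <- daily_regressions(ph, M)
  expect_lt(mean(dr$r2), 0.15)
})

test_that("the profile smoother preserves constants and tracks smooth signal", {
  expect_equal(smooth_profile(rep(3.5, 50), basis_dim = 20), rep(3.5, 50),
               tolerance = 1e-6)
  # curved input: the spline must do at least as well as the best line
  lag <- 1:120
  curved <- (lag - 60)^2 / 500
  sm <- smooth_profile(curved, lag, basis_dim = 20)
  line_rss <- sum(stats::resid(stats::lm(curved ~ lag))^2)
  expect_lte(sum((curved - sm)^2), line_rss)
  # noisy sine: smoothing reduces RMSE to the truth
  set.seed(105)
  truth <- sin(2 * pi * (1:365) / 180)
  noisy <- truth + stats::rnorm(365, 0, 0.4)
  sm2 <- smooth_profile(noisy, 1:365)
  expect_lt(sqrt(mean((sm2 - truth)^2)), sqrt(mean((noisy - truth)^2)))
  expect_error(smooth_profile(1:20, basis_dim = 20), "basis_dim")
  expect_error(smooth_profile(1:5), "at least 10")
})

test_that("the quantile rule extracts a constructed critical window exactly", {
  lag <- 1:365
  coef <- ifelse(lag >= 40 & lag <= 80, -5, 0)
  r2 <- ifelse(lag >= 40 & lag <= 80, 0.8, 0.05)
  prof <- structure(list(
    profile = data.frame(lag = lag, coef = coef, r2 = r2,
                         coef_smooth = coef, r2_smooth = r2),
    coef_tail = "auto", lower_q = 0.025, upper_q = 0.975,
    reference_day = "05-20"), class = "pc_csp_profile")
  out <- extract_critical_window(prof)
  expect_equal(out$critical$open, 80)
  expect_equal(out$critical$close, 40)
  # thresholds agree with an independently computed type-7 quantile
  expect_equal(out$coef_threshold, manual_quantile7(coef, 0.025))
  expect_equal(out$r2_threshold, manual_quantile7(r2, 0.975))
  expect_equal(out$tail_side, "lower")
  # flat profiles cannot single out a window
  flat <- prof
  flat$profile$coef_smooth <- rep(1, 365)
  flat$profile$r2_smooth <- rep(0.5, 365)
  expect_error(extract_critical_window(flat), "flat")
})

test_that("the critical window is invariant to a uniform temperature shift", {
  sim <- planted_window_sim(seed = 106, n_years = 40)
  M <- build_climate_matrix(sim$climate, sim$phenology$year)
  p1 <- csp_profile(sim$phenology, M, basis_dim = 30, relax = TRUE)
  M2 <- M
  M2[] <- unclass(M) + 3.7
  p2 <- csp_profile(sim$phenology, M2, basis_dim = 30, relax = TRUE)
  expect_equal(p1$critical, p2$critical)
  expect_equal(p1$profile$coef, p2$profile$coef, tolerance = 1e-8)
})

test_that("the CSP cue over the SWA window reproduces the SWA fit", {
  sim <- planted_window_sim(seed = 107, n_years = 30)
  M <- build_climate_matrix(sim$climate, sim$phenology$year)
  scan <- search_absolute(sim$phenology, M, statistics = "mean")
  cue <- fit_csp_cue(sim$phenology, M,
                     list(open = scan$best$window$open,
                          close = scan$best$window$close))
  expect_equal(cue$fit$intercept, scan$best$fit$intercept, tolerance = 1e-10)
  expect_equal(cue$fit$slope, scan$best$fit$slope, tolerance = 1e-10)
  expect_equal(cue$fit$r2_adj, scan$best$fit$r2_adj, tolerance = 1e-10)
})

test_that("a noise-free planted window gives an essentially perfect CSP cue", {
  years <- 1981:2010
  cl <- simulate_climate(years, seed = 108)
  sim <- simulate_phenology(
    cl, years, mechanism = "window",
    truth = list(window = list(open = 80, close = 40, statistic = "mean"),
                 intercept = 76, slope = -6),
    noise_sd = 0, seed = 109)
  M <- build_climate_matrix(cl, years)
  cue <- fit_csp_cue(sim$phenology, M, list(open = 80, close = 40))
  expect_gt(cue$fit$r2, 0.99) # whole-day rounding is the only noise
})

test_that("CSP critical windows overlap the planted sensitive period", {
  # The quantile rule marks only the extreme ~2.5% of lags, so on a planted
  # window whose days are all about equally informative it selects a short
  # sub-segment somewhere inside the sensitive period rather than centring
  # on it; the meaningful recovery property is overlap, not midpoint match.
  hits <- 0L
  for (s in 1:20) {
    sim <- planted_window_sim(seed = 200 + s)
    M <- build_climate_matrix(sim$climate, sim$phenology$year)
    prof <- csp_profile(sim$phenology, M, relax = TRUE)
    if (prof$critical$close <= 81 && prof$critical$open >= 14) hits <- hits + 1L
  }
  expect_gte(hits, 14L) # >= 70% of 20 replicates overlap lags 81..14
})
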