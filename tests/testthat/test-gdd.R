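gdd_fixture <- function(seed, n_years = 50, noise_sd = 1,
                        truth = list(start_day = 60, base_temp = 4,
                                     requirement = 200)) {
  years <- 1960 + seq_len(n_years)
  cl <- simulate_climate(years, seed = seed)
  sim <- simulate_phenology(cl, years, mechanism = "gdd", truth = truth,
                            noise_sd = noise_sd, seed = seed + 1,
                            bounds = c(-50, 250))
  list(cl = cl, ph = sim$phenology, truth = truth)
}

fast_ctl <- list(maxit = 800, restarts = 1)

test_that("degree-day accumulation crosses the requirement on the right day", {
  # constant 10 degC, Tb 5: 5 degree-days per day, requirement 25 -> day 5
  expect_equal(gdd_event_date(rep(10, 30),
                              list(start_day = 1, base_temp = 5,
                                   requirement = 25)), 5L)
  # hand-worked: increments 4,2,5,0,8 from day 2; cumulative crosses 10 on day 4
  expect_equal(gdd_event_date(c(2, 8, 6, 9, 1, 12),
                              list(start_day = 2, base_temp = 4,
                                   requirement = 10)), 4L)
  # requirement unattainable -> NOT_REACHED sentinel
  expect_true(is.na(gdd_event_date(rep(15, 100),
                                   list(start_day = 1, base_temp = 20,
                                        requirement = 50))))
  expect_error(gdd_event_date(c(1, NA, 3),
                              list(start_day = 1, base_temp = 0,
                                   requirement = 2)), "gaps")
})

test_that("accumulation matches a naive day-loop oracle on random series", {
  set.seed(601)
  for (i in 1:100) {
    temps <- stats::runif(120, -2, 18)
    t0 <- sample(1:60, 1)
    tb <- stats::runif(1, 1, 10)
    fstar <- stats::runif(1, 5, 400)
    got <- gdd_event_date(temps, list(start_day = t0, base_temp = tb,
                                      requirement = fstar))
    expect_identical(got, naive_gdd(temps, t0, tb, fstar))
  }
})

test_that("event dates respond monotonically to requirement and temperature", {
  set.seed(602)
  for (i in 1:250) {
    temps <- stats::runif(200, 0, 16)
    t0 <- sample(1:100, 1)
    tb <- stats::runif(1, 1, 10)
    f1 <- stats::runif(1, 20, 300)
    f2 <- f1 + stats::runif(1, 1, 200)
    p <- function(f, tt) gdd_event_date(tt, list(start_day = t0,
                                                 base_temp = tb,
                                                 requirement = f))
    e1 <- p(f1, temps); e2 <- p(f2, temps)
    # larger requirement never gives an earlier event
    if (!is.na(e2)) expect_lte(e1, e2)
    # warming any single day never delays the event
    warmed <- temps
    j <- sample(seq_along(temps), 1)
    warmed[j] <- warmed[j] + stats::runif(1, 0, 5)
    e1w <- p(f1, warmed)
    if (!is.na(e1)) expect_lte(e1w, e1)
  }
})

test_that("the vectorized multi-year predictor agrees with the scalar path", {
  fx <- gdd_fixture(603, n_years = 8)
  TM <- phenocue:::climate_doy_matrix(fx$cl, fx$ph$year)
  par <- c(60, 4, 200)
  vec <- phenocue:::gdd_predict_doy(TM, par)
  for (i in seq_along(fx$ph$year)) {
    expect_equal(vec$doy[i],
                 gdd_event_date(TM[i, ], list(start_day = 60, base_temp = 4,
                                              requirement = 200)))
  }
})

test_that("the true parameters are optimal on noise-free data", {
  fx <- gdd_fixture(604, n_years = 20, noise_sd = 0)
  TM <- phenocue:::climate_doy_matrix(fx$cl, fx$ph$year)
  obs_doy <- fx$ph$event_day + phenocue:::april1_doy(fx$ph$year) - 1L
  truth_par <- c(60, 4, 200)
  f_true <- phenocue:::gdd_objective(truth_par, TM, obs_doy, "direct")
  set.seed(605)
  for (i in 1:100) {
    rnd <- c(stats::runif(1, 1, 200), stats::runif(1, 1, 10),
             stats::runif(1, 50, 1000))
    expect_lte(f_true, phenocue:::gdd_objective(rnd, TM, obs_doy, "direct"))
  }
})

test_that("fitting is deterministic under a fixed seed", {
  fx <- gdd_fixture(606, n_years = 25)
  f1 <- fit_gdd(fx$ph, fx$cl, seed = 99, control = fast_ctl)
  f2 <- fit_gdd(fx$ph, fx$cl, seed = 99, control = fast_ctl)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective_value, f2$objective_value)
  expect_error(fit_gdd(fx$ph, fx$cl,
                       bounds = list(start_day = c(200, 1),
                                     base_temp = c(1, 10),
                                     requirement = c(50, 1000))),
               "inverted")
})

test_that("both objective modes are exposed and finite", {
  fx <- gdd_fixture(607, n_years = 20)
  fd <- fit_gdd(fx$ph, fx$cl, objective = "direct", seed = 1,
                control = fast_ctl)
  fr <- fit_gdd(fx$ph, fx$cl, objective = "regression", seed = 1,
                control = fast_ctl)
  expect_true(is.finite(fd$objective_value))
  expect_true(is.finite(fr$objective_value))
  expect_equal(fr$objective_mode, "regression")
})

test_that("bootstrap intervals are well-formed, seeded and bracket the fit", {
  fx0 <- gdd_fixture(608, n_years = 25, noise_sd = 0)
  fx3 <- gdd_fixture(608, n_years = 25, noise_sd = 3)
  f0 <- fit_gdd(fx0$ph, fx0$cl, seed = 7, control = fast_ctl)
  f3 <- fit_gdd(fx3$ph, fx3$cl, seed = 7, control = fast_ctl)
  b0 <- suppressWarnings(bootstrap_gdd(f0, fx0$ph, fx0$cl, reps = 30,
                                       seed = 8, boot_maxit = 150))
  expect_equal(dim(b0$boot_params), c(30L, 3L))
  expect_true(all(b0$ci_low <= b0$ci_high))
  # identical seed reproduces the bootstrap distribution exactly
  b0b <- suppressWarnings(bootstrap_gdd(f0, fx0$ph, fx0$cl, reps = 30,
                                        seed = 8, boot_maxit = 150))
  expect_identical(b0$boot_params, b0b$boot_params)
  # training error tracks phenology noise (the parameter intervals do not:
  # their width is dominated by the base-temperature/requirement ridge)
  expect_lt(mean(abs(f0$predicted - fx0$ph$event_day)),
            mean(abs(f3$predicted - fx3$ph$event_day)))
  expect_error(bootstrap_gdd(f0, fx0$ph, fx0$cl, reps = 1), "at least 2")
})

test_that("point estimates usually fall inside their bootstrap intervals", {
  inside <- 0L
  for (s in 1:10) {
    fx <- gdd_fixture(620 + s, n_years = 25)
    f <- fit_gdd(fx$ph, fx$cl, seed = s, control = fast_ctl)
    b <- suppressWarnings(bootstrap_gdd(f, fx$ph, fx$cl, reps = 25,
                                        seed = s + 50, boot_maxit = 120))
    if (all(b$params >= b$ci_low & b$params <= b$ci_high)) inside <- inside + 1L
  }
  expect_gte(inside, 9L)
})

test_that("GDD predictions collapse with degenerate intervals and track warming", {
  fx <- gdd_fixture(640, n_years = 20)
  f <- fit_gdd(fx$ph, fx$cl, seed = 3, control = fast_ctl)
  # degenerate CIs: interval collapses onto the point prediction
  f$ci_low <- f$ci_high <- unname(f$params)
  names(f$ci_low) <- names(f$ci_high) <- names(f$params)
  p <- predict_gdd(f, fx$cl, fx$ph$year[1:5])
  expect_equal(p$pi_low, p$predicted)
  expect_equal(p$pi_high, p$predicted)
  # a uniformly warmer year never delays the predicted event
  cl2 <- fx$cl
  cl2$temp <- cl2$temp + 2
  p2 <- predict_gdd(f, cl2, fx$ph$year[1:5])
  expect_true(all(p2$predicted <= p$predicted))
})
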