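# Penalized B-spline signal regression (PSR).
#
# The annual mean event day is regressed on the whole year of daily mean
# temperatures at once. The 365 partial coefficients are constrained to a
# cubic B-spline basis over lag and roughness is penalized through
# first-order differences of the basis coefficients:
#
#   minimize ||y - alpha - X B theta||^2 + lambda ||D theta||^2
#
# with X the years-by-lags temperature matrix, B the B-spline basis
# evaluated at the lags, D the first-difference operator, and lambda chosen
# by generalized cross-validation over a log-spaced grid. The coefficient
# function is beta(lag) = B theta (days per degree C per day); its pointwise
# standard errors come from the penalized-least-squares covariance
# sigma^2 * M^-1 G M^-1 with M = Z'Z + P and G = Z'Z.

psr_basis <- function(lags, knots, degree) {
  lo <- min(lags); hi <- max(lags)
  inner <- seq(lo, hi, length.out = knots - degree + 1)
  kv <- c(rep(lo, degree), inner, rep(hi, degree))
  B <- splines::splineDesign(kv, as.numeric(lags), ord = degree + 1)
  stopifnot(ncol(B) == knots)
  B
}

psr_solve <- function(Z, y, P, lambda) {
  M <- crossprod(Z) + lambda * P
  R <- chol(M)
  coef <- backsolve(R, forwardsolve(t(R), crossprod(Z, y)))
  fitted <- as.numeric(Z %*% coef)
  # edf = tr(Z M^-1 Z') = sum over entries of (Z M^-1) * Z
  ZMi <- t(backsolve(R, forwardsolve(t(R), t(Z))))
  edf <- sum(ZMi * Z)
  list(coef = as.numeric(coef), fitted = fitted, edf = edf, M_chol = R)
}

#' Fit a penalized B-spline signal regression
#'
#' @param phenology A [pheno_series()].
#' @param matrix A `climate_matrix` covering the phenology years (the full
#'   lag range is used as the functional covariate, in raw degrees C).
#' @param knots Number of B-spline basis functions (default 20); must not
#'   exceed the number of years minus 2.
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order Order of the difference penalty (default 1).
#' @param lambda Fixed smoothing parameter; `NULL` (default) selects it by
#'   GCV over `lambda_grid`.
#' @param lambda_grid Log-spaced candidate grid for GCV.
#' @return An object of class `pc_psr_model`: list with `intercept`, `beta`
#'   and `beta_se` (per lag), `lags`, `theta`, `lambda`, `gcv` (data frame
#'   over the grid when selected), `edf`, `sigma2`, `fitted`, `r2`,
#'   `r2_adj`, `n`, plus internals needed for prediction.
#' @export
fit_psr <- function(phenology, matrix, knots = 20, degree = 3,
                    penalty_order = 1, lambda = NULL,
                    lambda_grid = 10^seq(-4, 6, length.out = 41)) {
  stopifnot(inherits(phenology, "pheno_series"),
            inherits(matrix, "climate_matrix"))
  matrix <- subset_years(matrix, phenology$year)
  y <- as.numeric(phenology$event_day)
  n <- length(y)
  if (n < 5) stop("need at least 5 years to fit the signal regression")
  if (knots > n - 2)
    stop("number of knots (", knots, ") cannot exceed one less than the ",
         "sample size minus one (n - 2 = ", n - 2, ")")
  lags <- attr(matrix, "lags")
  X <- unclass(matrix)
  B <- psr_basis(lags, knots, degree)
  Z <- cbind(1, X %*% B)
  D <- diff(diag(knots), differences = penalty_order)
  P <- rbind(0, cbind(0, crossprod(D))) # intercept unpenalized
  gcv_tab <- NULL
  if (is.null(lambda)) {
    gcv_tab <- data.frame(lambda = lambda_grid, gcv = NA_real_)
    for (i in seq_along(lambda_grid)) {
      s <- psr_solve(Z, y, P, lambda_grid[i])
      rss <- sum((y - s$fitted)^2)
      gcv_tab$gcv[i] <- n * rss / (n - s$edf)^2
    }
    lambda <- gcv_tab$lambda[which.min(gcv_tab$gcv)]
  }
  s <- psr_solve(Z, y, P, lambda)
  rss <- sum((y - s$fitted)^2)
  sigma2 <- rss / (n - s$edf)
  # covariance of all coefficients (intercept + theta)
  Mi <- chol2inv(s$M_chol)
  G <- crossprod(Z)
  V <- sigma2 * Mi %*% G %*% Mi
  beta <- as.numeric(B %*% s$coef[-1])
  Vtheta <- V[-1, -1, drop = FALSE]
  beta_se <- sqrt(pmax(rowSums((B %*% Vtheta) * B), 0))
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - rss / syy else 0
  structure(list(
    intercept = s$coef[1], theta = s$coef[-1], beta = beta, beta_se = beta_se,
    lags = lags, knots = knots, degree = degree,
    penalty_order = penalty_order, lambda = lambda, gcv = gcv_tab,
    edf = s$edf, sigma2 = sigma2, rss = rss, fitted = s$fitted,
    r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - s$edf),
    n = n, years = phenology$year, basis = B, coef_cov = V,
    reference_day = attr(matrix, "reference_day")
  ), class = "pc_psr_model")
}

#' Lags with coefficients distinguishable from zero
#'
#' Flags the lags whose partial coefficient differs from zero by more than
#' twice its pointwise standard error.
#'
#' @param model A `pc_psr_model`.
#' @return Integer vector of flagged lags (possibly empty).
#' @export
important_days <- function(model) {
  stopifnot(inherits(model, "pc_psr_model"))
  model$lags[abs(model$beta) > 2 * model$beta_se]
}

#' Predict event days from a signal-regression model
#'
#' Point prediction is `alpha + sum_d beta(d) * X_new(d)`; the prediction
#' interval is `yhat +/- t * sqrt(se_fit^2 + sigma^2)` with residual degrees
#' of freedom `n - edf`.
#'
#' @param model A `pc_psr_model`.
#' @param matrix A `climate_matrix` for the test years with the same lag
#'   layout as the training matrix.
#' @param level Interval coverage, default 0.95.
#' @return A `pc_predictions` data frame (year, predicted, pi_low, pi_high).
#' @export
predict_psr <- function(model, matrix, level = 0.95) {
  stopifnot(inherits(model, "pc_psr_model"), inherits(matrix, "climate_matrix"))
  if (!identical(as.integer(attr(matrix, "lags")), as.integer(model$lags)))
    stop("lag layout of the test matrix does not match the training matrix")
  Znew <- cbind(1, unclass(matrix) %*% model$basis)
  coefs <- c(model$intercept, model$theta)
  yhat <- as.numeric(Znew %*% coefs)
  se_fit2 <- pmax(rowSums((Znew %*% model$coef_cov) * Znew), 0)
  tq <- stats::qt((1 + level) / 2, df = model$n - model$edf)
  half <- tq * sqrt(se_fit2 + model$sigma2)
  structure(data.frame(year = attr(matrix, "years"), predicted = yhat,
                       pi_low = yhat - half, pi_high = yhat + half),
            class = c("pc_predictions", "data.frame"))
}

#' @export
print.pc_psr_model <- function(x, ...) {
  imp <- important_days(x)
  win <- if (length(imp)) paste0(max(imp), "..", min(imp)) else "none"
  cat(sprintf(
    "<pc_psr_model> n=%d  %d basis fns (degree %d, penalty order %d)  lambda=%.3g  edf=%.1f  adj R2=%.3f  important lags: %s\n",
    x$n, x$knots, x$degree, x$penalty_order, x$lambda, x$edf, x$r2_adj, win))
  invisible(x)
}
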