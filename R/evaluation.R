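# Predictive evaluation: training/test split plans, re-identification of
# the cue on each training set, out-of-sample prediction, and the accuracy
# and precision metrics (MAE, mean signed error, prediction-interval width,
# coverage) plus the least-squares trend of prediction error through time.

#' Mean absolute error
#' @param predicted,observed Aligned numeric vectors.
#' @return Mean of `|predicted - observed|`, in days.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) == 0) stop("empty input")
  mean(abs(predicted - observed))
}

#' Mean signed prediction error
#' @inheritParams mae
#' @return Mean of `predicted - observed` (negative = predictions precede
#'   observations), in days.
#' @export
mean_signed_error <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) == 0) stop("empty input")
  mean(predicted - observed)
}

#' Prediction-interval coverage
#' @param pi_low,pi_high Interval bounds.
#' @param observed Observed values.
#' @return Fraction of observations with `pi_low <= obs <= pi_high`
#'   (closed interval).
#' @export
coverage <- function(pi_low, pi_high, observed) {
  if (length(pi_low) != length(observed) || length(pi_high) != length(observed))
    stop("length mismatch")
  mean(observed >= pi_low & observed <= pi_high)
}

#' Least-squares trend of prediction error through time
#'
#' @param errors Per-fold mean signed errors (days).
#' @param mid_years Time coordinate of each fold (fold mid-year).
#' @return List with `slope` (days per year) and `r2` (multiple R-squared).
#' @export
error_trend <- function(errors, mid_years) {
  if (length(errors) < 3) stop("need at least 3 folds for an error trend")
  if (stats::var(errors) == 0) return(list(slope = 0, r2 = 0))
  f <- fit_linear(mid_years, errors)
  list(slope = f$slope, r2 = f$r2)
}

#' Build a training/test split plan
#'
#' Three designs:
#' * `near_future`: the full range plus shrunken subsets in `increment`-year
#'   steps from both ends (for a 50-year range with 10-year increments this
#'   gives nine training sets); each is tested on the `test_width` years
#'   directly following its end.
#' * `fixed_test`: the same training sets, all tested on the `test_width`
#'   years after the full range.
#' * `kfold`: the range is partitioned into `test_width`-year folds; each
#'   fold is predicted from the complementary years.
#'
#' @param full Length-2 integer (first and last year) or an integer vector
#'   of consecutive years.
#' @param increment Shrink step in years (default 10; near_future /
#'   fixed_test modes).
#' @param test_width Test-span width in years (default 5).
#' @param mode One of `"near_future"`, `"fixed_test"`, `"kfold"`.
#' @return An object of class `pc_split_plan`: list of splits, each with
#'   `train`, `test` (year vectors) and `label`, plus attributes `mode` and
#'   `test_width`.
#' @export
make_training_sets <- function(full, increment = 10, test_width = 5,
                               mode = c("near_future", "fixed_test", "kfold")) {
  mode <- match.arg(mode)
  full <- if (length(full) == 2) full[1]:full[2] else as.integer(full)
  stopifnot(all(diff(full) == 1L))
  start <- min(full); end <- max(full)
  n <- length(full)
  if (mode %in% c("near_future", "fixed_test")) {
    if (n < 2 * increment)
      stop("range must span at least two increments")
    if (n %% increment != 0)
      stop("increment (", increment, ") does not divide the range (",
           n, " years)")
    k <- n %/% increment
    trains <- c(list(start:end),
                lapply(seq_len(k - 1), function(i) (start + i * increment):end),
                lapply(seq_len(k - 1), function(i) start:(end - i * increment)))
    splits <- lapply(trains, function(tr) {
      te <- if (mode == "near_future") (max(tr) + 1):(max(tr) + test_width)
            else (end + 1):(end + test_width)
      list(train = tr, test = te,
           label = paste0(min(tr), "-", max(tr)))
    })
  } else {
    if (n %% test_width != 0)
      stop("test_width (", test_width, ") does not divide the range (",
           n, " years)")
    folds <- split(full, rep(seq_len(n %/% test_width), each = test_width))
    splits <- lapply(folds, function(te) {
      list(train = setdiff(full, te), test = te,
           label = paste0("fold ", min(te), "-", max(te)))
    })
    names(splits) <- NULL
  }
  structure(splits, class = "pc_split_plan", mode = mode,
            test_width = test_width)
}

#' @export
print.pc_split_plan <- function(x, ...) {
  cat("<pc_split_plan> mode ", attr(x, "mode"), ", ", length(x),
      " splits\n", sep = "")
  for (s in x)
    cat(sprintf("  train %d-%d (%d yrs) -> test %d-%d\n", min(s$train),
                max(s$train), length(s$train), min(s$test), max(s$test)))
  invisible(x)
}

subset_pheno <- function(phenology, years) {
  keep <- phenology$year %in% years
  if (sum(keep) == 0) stop("no phenology data for requested years")
  pheno_series(phenology$year[keep], phenology$event_day[keep],
               bounds = attr(phenology, "bounds") %||% c(1, 120))
}

fit_and_predict <- function(method, ph_tr, M_tr, M_te, climate, test_years,
                            seed, control) {
  if (method == "swa") {
    scan <- search_absolute(ph_tr, M_tr, statistics = control$statistics,
                            max_duration = control$max_duration)
    list(pred = predict_from_cue(scan$best, M_te),
         window_open = scan$best$window$open,
         window_close = scan$best$window$close)
  } else if (method == "csp") {
    prof <- csp_profile(ph_tr, M_tr, basis_dim = control$csp_basis_dim,
                        relax = TRUE)
    cue <- fit_csp_cue(ph_tr, M_tr, prof)
    list(pred = predict_from_cue(cue, M_te),
         window_open = prof$critical$open, window_close = prof$critical$close)
  } else if (method == "psr") {
    # short training sets cap the basis size (knots <= n - 2)
    mod <- fit_psr(ph_tr, M_tr,
                   knots = min(control$psr_knots, nrow(ph_tr) - 2))
    imp <- important_days(mod)
    list(pred = predict_psr(mod, M_te),
         window_open = if (length(imp)) max(imp) else NA_integer_,
         window_close = if (length(imp)) min(imp) else NA_integer_)
  } else if (method == "gdd") {
    fit <- fit_gdd(ph_tr, climate, seed = seed,
                   control = list(maxit = control$gdd_maxit,
                                  restarts = control$gdd_restarts))
    fit <- bootstrap_gdd(fit, ph_tr, climate, reps = control$gdd_boot_reps,
                         seed = seed + 1L, boot_maxit = control$gdd_boot_maxit)
    list(pred = predict_gdd(fit, climate, test_years),
         window_open = NA_integer_, window_close = NA_integer_)
  } else stop("unknown method: ", method)
}

default_eval_control <- function() {
  list(statistics = WINDOW_STATISTICS, max_duration = 365,
       csp_basis_dim = 50, psr_knots = 20,
       gdd_maxit = 2000, gdd_restarts = 2,
       gdd_boot_reps = 100, gdd_boot_maxit = 300)
}

#' Run a prediction experiment
#'
#' For each split of the plan, re-identifies every method's cue on the
#' training years alone (full re-identification, never reuse of a global
#' cue), predicts the test years, and computes MAE, mean signed error,
#' prediction-interval width and coverage. On plans with at least three
#' splits the least-squares trend of per-fold mean signed error against
#' fold mid-year is reported, both per method and pooled (all methods, and
#' the regression-based subset SWA/CSP/PSR), in stacked (method-by-fold
#' points) and fold-mean pooling variants.
#'
#' The relative sliding window cannot predict (its window is anchored to
#' the event); if requested it is dropped with a message.
#'
#' @param phenology A [pheno_series()] covering all plan years.
#' @param climate A [climate_series()] with full coverage.
#' @param methods Subset of `c("swa", "csp", "psr", "gdd")` (`"swr"` is
#'   accepted but dropped).
#' @param plan A `pc_split_plan` from [make_training_sets()].
#' @param reference_day Calendar anchor for absolute lags.
#' @param seed Integer seed (drives the GDD fits).
#' @param control List overriding [default_eval_control()] entries
#'   (window statistics, max duration, CSP basis dimension, PSR knots, GDD
#'   search and bootstrap budgets).
#' @return An object of class `pc_eval_report`: list with `predictions`,
#'   `metrics` (per method and split), `summary` (per method, pooled over
#'   splits), `trend`, `plan`, `seed`.
#' @export
run_experiment <- function(phenology, climate,
                           methods = c("swa", "csp", "psr", "gdd"),
                           plan, reference_day = "05-20", seed = 1,
                           control = list()) {
  stopifnot(inherits(plan, "pc_split_plan"))
  control <- utils::modifyList(default_eval_control(), control)
  if ("swr" %in% methods) {
    message("dropping 'swr': a relative window is defined by the event ",
            "date itself, so it cannot be used predictively")
    methods <- setdiff(methods, "swr")
  }
  methods <- match.arg(methods, c("swa", "csp", "psr", "gdd"),
                       several.ok = TRUE)
  all_years <- sort(unique(unlist(lapply(plan, function(s) c(s$train, s$test)))))
  if (!all(all_years %in% phenology$year))
    stop("phenology does not cover all plan years")
  M_all <- build_climate_matrix(climate, all_years, reference_day)
  preds <- list(); metrics <- list()
  for (si in seq_along(plan)) {
    s <- plan[[si]]
    ph_tr <- subset_pheno(phenology, s$train)
    ph_te <- subset_pheno(phenology, s$test)
    M_tr <- subset_years(M_all, s$train)
    M_te <- subset_years(M_all, s$test)
    for (m in methods) {
      fp <- fit_and_predict(m, ph_tr, M_tr, M_te, climate, s$test,
                            seed = seed + 1000L * si, control = control)
      p <- fp$pred
      obs <- ph_te$event_day[match(p$year, ph_te$year)]
      preds[[length(preds) + 1]] <- data.frame(
        split = s$label, method = m, year = p$year, observed = obs,
        predicted = p$predicted, pi_low = p$pi_low, pi_high = p$pi_high)
      metrics[[length(metrics) + 1]] <- data.frame(
        split = s$label, method = m,
        mid_year = mean(s$test),
        mae = mae(p$predicted, obs),
        mean_signed_error = mean_signed_error(p$predicted, obs),
        pi_width = mean(p$pi_high - p$pi_low),
        coverage = coverage(p$pi_low, p$pi_high, obs),
        window_open = fp$window_open, window_close = fp$window_close)
    }
  }
  preds <- do.call(rbind, preds)
  metrics <- do.call(rbind, metrics)
  summary <- do.call(rbind, lapply(methods, function(m) {
    pm <- preds[preds$method == m, ]
    data.frame(method = m,
               mae = mae(pm$predicted, pm$observed),
               mean_signed_error = mean_signed_error(pm$predicted, pm$observed),
               pi_width = mean(pm$pi_high - pm$pi_low),
               coverage = coverage(pm$pi_low, pm$pi_high, pm$observed),
               n_pred = nrow(pm))
  }))
  trend <- NULL
  if (length(plan) >= 3) {
    trend_row <- function(scope, mm) {
      sub <- metrics[metrics$method %in% mm, ]
      tr <- error_trend(sub$mean_signed_error, sub$mid_year)
      fm <- stats::aggregate(mean_signed_error ~ mid_year, sub, mean)
      trf <- if (nrow(fm) >= 3) error_trend(fm$mean_signed_error, fm$mid_year)
             else list(slope = NA_real_, r2 = NA_real_)
      data.frame(scope = scope, slope = tr$slope, r2 = tr$r2,
                 slope_foldmean = trf$slope, r2_foldmean = trf$r2)
    }
    rows <- lapply(methods, function(m) trend_row(m, m))
    rows <- c(rows, list(trend_row("all", methods)))
    regm <- intersect(methods, c("swa", "csp", "psr"))
    if (length(regm) > 0)
      rows <- c(rows, list(trend_row("regression_based", regm)))
    trend <- do.call(rbind, rows)
  }
  structure(list(predictions = preds, metrics = metrics, summary = summary,
                 trend = trend, plan = plan, seed = seed),
            class = "pc_eval_report")
}

#' @export
print.pc_eval_report <- function(x, ...) {
  cat("<pc_eval_report> ", length(x$plan), " splits (",
      attr(x$plan, "mode"), "), methods: ",
      paste(unique(x$summary$method), collapse = ", "), "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
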