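# Run configuration, batch driver and deposited-data reproduction.
#
# A run configuration is a YAML-serializable list validated against a fixed
# schema (unknown keys are rejected so typos fail loudly). pc_run() executes
# a full analysis deterministically from (config, seed) and writes CSV
# outputs plus a manifest echoing the configuration and package version.

RUN_CONFIG_KEYS <- c(
  "seed", "reference_day", "out_dir", "methods", "mode", "increment",
  "test_width", "train", "kfold_range", "phenology", "climate", "scenario",
  "statistics", "max_duration", "csp_basis_dim", "psr_knots",
  "gdd_maxit", "gdd_restarts", "gdd_boot_reps", "gdd_boot_maxit")

#' Validate / read a run configuration
#'
#' @param config A named list (see [pc_run()] for recognized fields).
#' @param path Path to a YAML file.
#' @return The validated configuration list, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, reference_day = "05-20",
                   methods = c("swa", "swr", "csp", "psr", "gdd"),
                   mode = "kfold", increment = 10L, test_width = 5L)
  config <- utils::modifyList(defaults, config)
  if (!grepl("^\\d{2}-\\d{2}$", config$reference_day))
    stop("reference_day must be 'MM-DD'")
  bad <- setdiff(config$methods, c("swa", "swr", "csp", "psr", "gdd"))
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  config
}

#' @rdname validate_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

method_table_row <- function(method, statistic, fit, open, close) {
  data.frame(method = method, statistic = statistic,
             intercept = if (is.null(fit)) NA_real_ else fit$intercept,
             slope = if (is.null(fit)) NA_real_ else fit$slope,
             se = if (is.null(fit)) NA_real_ else fit$slope_se,
             r2_adj = if (is.null(fit)) NA_real_ else fit$r2_adj,
             window_open = open, window_close = close)
}

#' Identify cues with every method on one training period
#'
#' Runs the five identification methods on the given years and summarizes
#' each fitted cue model as one row: aggregate statistic, intercept, slope,
#' standard error, adjusted R-squared and the window open/close lags.
#'
#' @param phenology,climate The data.
#' @param years Training years.
#' @param reference_day Calendar anchor (default `"05-20"`).
#' @param seed Seed for the GDD search.
#' @param control Overrides for [default_eval_control()] entries.
#' @param methods Which methods to run.
#' @return List with `table` (one row per method), `fits` (the fitted
#'   objects), `gdd_params` (point estimates and, when bootstrapped, CIs).
#' @export
identify_cues <- function(phenology, climate, years,
                          reference_day = "05-20", seed = 1,
                          control = list(),
                          methods = c("swa", "swr", "csp", "psr", "gdd")) {
  control <- utils::modifyList(default_eval_control(), control)
  ph <- subset_pheno(phenology, years)
  M <- build_climate_matrix(climate, years, reference_day)
  rows <- list(); fits <- list(); gdd_params <- NULL
  if ("swa" %in% methods) {
    scan <- search_absolute(ph, M, statistics = control$statistics,
                            max_duration = control$max_duration)
    fits$swa <- scan
    rows$swa <- method_table_row("swa", scan$best$window$statistic,
                                 scan$best$fit, scan$best$window$open,
                                 scan$best$window$close)
  }
  if ("swr" %in% methods) {
    scan <- search_relative(ph, climate, statistics = control$statistics,
                            max_duration = control$max_duration)
    fits$swr <- scan
    rows$swr <- method_table_row("swr", scan$best$window$statistic,
                                 scan$best$fit, scan$best$window$open,
                                 scan$best$window$close)
  }
  if ("csp" %in% methods) {
    prof <- csp_profile(ph, M, basis_dim = control$csp_basis_dim,
                        relax = TRUE)
    cue <- fit_csp_cue(ph, M, prof)
    fits$csp <- list(profile = prof, cue = cue)
    rows$csp <- method_table_row("csp", "mean", cue$fit,
                                 prof$critical$open, prof$critical$close)
  }
  if ("psr" %in% methods) {
    mod <- fit_psr(ph, M, knots = min(control$psr_knots, nrow(ph) - 2))
    fits$psr <- mod
    imp <- important_days(mod)
    rows$psr <- data.frame(method = "psr", statistic = "daily_mean",
                           intercept = mod$intercept, slope = NA_real_,
                           se = NA_real_, r2_adj = mod$r2_adj,
                           window_open = if (length(imp)) max(imp) else NA,
                           window_close = if (length(imp)) min(imp) else NA)
  }
  if ("gdd" %in% methods) {
    fit <- fit_gdd(ph, climate, seed = seed,
                   control = list(maxit = control$gdd_maxit,
                                  restarts = control$gdd_restarts))
    fits$gdd <- fit
    rows$gdd <- method_table_row("gdd", "degree_day_sum", fit$cue_fit,
                                 NA, NA)
    gdd_params <- data.frame(parameter = names(fit$params),
                             estimate = unname(fit$params))
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits, gdd_params = gdd_params)
}

#' Execute a run configuration
#'
#' Recognized fields: `seed`; `reference_day`; `out_dir`; data via either
#' `phenology` + `climate` (CSV paths) or `scenario` (a scenario list / YAML
#' path for [simulate_scenario()]); `train` (length-2 training range for cue
#' identification); `methods`; `mode`, `increment`, `test_width`,
#' `kfold_range` (evaluation plan); method hyperparameters `statistics`,
#' `max_duration`, `csp_basis_dim`, `psr_knots`, `gdd_maxit`,
#' `gdd_restarts`, `gdd_boot_reps`, `gdd_boot_maxit`.
#'
#' Writes `cue_models.csv` (one row per method), `gdd_params.csv`,
#' `metrics.csv`, `summary.csv`, `predictions.csv`, `trend.csv` (when the
#' plan has 3+ splits) and `manifest.yaml` into `out_dir`. Outputs are
#' deterministic given (config, seed).
#'
#' @param config A validated configuration list or a YAML path.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with `cues`, `report` and the paths written.
#' @export
pc_run <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$scenario)) {
    scen <- if (is.character(config$scenario)) yaml::read_yaml(config$scenario)
            else config$scenario
    if (isTRUE(scen$default) || identical(scen, "default"))
      scen <- default_scenario()
    sim <- simulate_scenario(scen, seed = config$seed)
    phenology <- sim$phenology; climate <- sim$climate
  } else {
    if (is.null(config$phenology) || is.null(config$climate))
      stop("configuration needs either 'scenario' or both 'phenology' and ",
           "'climate' paths")
    phenology <- read_phenology(config$phenology)
    climate <- read_climate(config$climate)
  }
  control <- config[intersect(names(config),
                              names(default_eval_control()))]
  train <- config$train %||% range(phenology$year)
  cues <- identify_cues(phenology, climate, train[1]:train[2],
                        reference_day = config$reference_day,
                        seed = config$seed, control = control,
                        methods = config$methods)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  w(cues$table, "cue_models.csv")
  if (!is.null(cues$gdd_params)) w(cues$gdd_params, "gdd_params.csv")
  report <- NULL
  if (!is.null(config$mode) && config$mode != "none") {
    plan_range <- config$kfold_range %||% train
    plan <- make_training_sets(plan_range, increment = config$increment,
                               test_width = config$test_width,
                               mode = config$mode)
    report <- run_experiment(phenology, climate,
                             methods = setdiff(config$methods, "swr"),
                             plan = plan,
                             reference_day = config$reference_day,
                             seed = config$seed, control = control)
    w(report$metrics, "metrics.csv")
    w(report$summary, "summary.csv")
    w(report$predictions, "predictions.csv")
    if (!is.null(report$trend)) w(report$trend, "trend.csv")
  }
  manifest <- list(package = "phenocue",
                   version = as.character(utils::packageVersion("phenocue")),
                   config = config[order(names(config))])
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  paths[["manifest.yaml"]] <- file.path(out_dir, "manifest.yaml")
  invisible(list(cues = cues, report = report, paths = paths))
}

#' Reproduce the headline analyses on a deposited-format dataset
#'
#' Given annual-phenology and daily-climate CSVs, identifies cues with all
#' five methods on the training range and runs the K-fold evaluation of the
#' four predictive methods, writing a cue-model table, a predictive-metrics
#' table, the error trend and all predictions.
#'
#' @param phenology_path,climate_path CSV paths (see [read_phenology()] and
#'   [read_climate()] for the accepted layouts).
#' @param out_dir Output directory.
#' @param train Length-2 training range for cue identification
#'   (default `c(1961, 2010)`).
#' @param kfold_range Length-2 range for the K-fold evaluation
#'   (default `c(1961, 2015)`).
#' @param seed Integer seed.
#' @param control Overrides for [default_eval_control()].
#' @return Invisibly, list with `cues` and `report`.
#' @export
reproduce_analysis <- function(phenology_path, climate_path, out_dir,
                               train = c(1961, 2010),
                               kfold_range = c(1961, 2015), seed = 1,
                               control = list()) {
  pc_run(list(phenology = phenology_path, climate = climate_path,
              train = train, kfold_range = kfold_range, mode = "kfold",
              seed = seed, out_dir = out_dir), out_dir = out_dir)
}
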