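#' Validate a pipeline configuration
#'
#' Checks structure and types before any computation: `data` (either a
#' `synthetic` block of [synthetic_spec()] arguments or `descriptors` +
#' `activity` CSV paths), `split` (`n_train`, `n_test`), `selection`
#' (`method` `"hm"` or `"gbm"` plus its parameters), and `models` (a subset
#' of the standard panel). Optional blocks: `tune`, `svr`, `rf`, `seed`,
#' `outdir`.
#'
#' @param config A named list (e.g. parsed from YAML).
#' @return The config, with defaults filled in, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  for (key in c("data", "split", "selection", "models")) {
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  }
  d <- config$data
  if (is.null(d$synthetic) && (is.null(d$descriptors) || is.null(d$activity))) {
    stop("config$data needs either a 'synthetic' block or ",
         "'descriptors' + 'activity' paths")
  }
  if (is.null(config$split$n_train) || is.null(config$split$n_test)) {
    stop("config$split needs n_train and n_test")
  }
  if (!config$selection$method %in% c("hm", "gbm")) {
    stop("selection$method must be 'hm' or 'gbm'")
  }
  known <- c("linear", "rf", "svr-linear", "svr-poly", "svr-rbf", "svr-mix")
  bad <- setdiff(unlist(config$models), known)
  if (length(bad) > 0) stop("unknown model(s): ", paste(bad, collapse = ", "))
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$outdir <- if (is.null(config$outdir)) "qsarmix_run" else config$outdir
  config
}

#' Run the full QSAR pipeline
#'
#' One call executes the whole analysis: load or generate the descriptor
#' matrix and activities, split into training and test compounds, pre-filter
#' and select descriptors (stepwise multilinear "heuristic method" or
#' gradient-boosting importance), optionally tune the mixed-kernel SVR or
#' random forest by particle swarm, fit the requested model panel, and
#' evaluate with train/test metrics and LOOCV. Descriptor selection and
#' tuning see only the training compounds. All artifacts are written to
#' `outdir`: `selection_curve.csv` or `importance.csv`, `pso_trace.csv`
#' (when tuning), `comparison.csv`, `predictions.csv`, and `run_log.txt`
#' recording the per-stage seeds and the package version. The master seed
#' fans out to stage seeds via `stage_seed()` (`(seed %% 1e6) * 1000 +
#' stage`), so a rerun with the same config reproduces every artifact.
#'
#' @param config A named list or a path to a YAML file.
#' @param seed,outdir Optional overrides of the config values.
#' @return Invisibly, a list with the selected descriptors, tuning result
#'   (or NULL), the `eval_report`, and the artifact paths.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run_log.txt")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("qsarmix %s | master seed %d",
       as.character(utils::packageVersion("qsarmix")), config$seed)
  stage <- "setup"
  on_fail <- function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "data"
    if (!is.null(config$data$synthetic)) {
      sp_args <- config$data$synthetic
      sp_args$seed <- stage_seed(config$seed, 1)
      sp <- do.call(synthetic_spec, sp_args)
      dat <- generate_synthetic(sp)
      x <- dat$descriptors; y <- dat$activity
      logf("generated synthetic data %d x %d (seed %d)",
           nrow(x), ncol(x), sp$seed)
    } else {
      x <- read_descriptor_matrix(config$data$descriptors)
      y <- read_activity(config$data$activity)
      y <- y[rownames(x)]
      logf("loaded %d x %d descriptors from %s", nrow(x), ncol(x),
           config$data$descriptors)
    }

    stage <- "split"
    records <- data.frame(id = rownames(x))
    split <- random_split(records, config$split$n_train, config$split$n_test,
                          seed = stage_seed(config$seed, 2))
    logf("split: %d train / %d test (seed %d)", length(split$train_ids),
         length(split$test_ids), stage_seed(config$seed, 2))
    xtr <- x[split$train_ids, , drop = FALSE]
    ytr <- y[split$train_ids]

    stage <- "selection"
    sel_cfg <- config$selection
    corr_thr <- if (is.null(sel_cfg$corr_threshold)) 0.8 else
      sel_cfg$corr_threshold
    surviving <- prefilter(xtr, ytr, corr_threshold = corr_thr)
    logf("prefilter: %d of %d descriptors survive", length(surviving),
         ncol(x))
    if (sel_cfg$method == "hm") {
      max_k <- if (is.null(sel_cfg$max_k)) 7 else sel_cfg$max_k
      curve <- stepwise_select(xtr[, surviving, drop = FALSE], ytr,
                               max_k = max_k, corr_threshold = corr_thr)
      delta <- if (is.null(sel_cfg$plateau_delta)) 0.01 else
        sel_cfg$plateau_delta
      chosen <- choose_model(curve, plateau_delta = delta)
      selected <- chosen$descriptors
      write_selection_curve(curve,
                            file.path(config$outdir, "selection_curve.csv"))
      logf("HM selection: k = %d, R2 = %.3f, R2cv = %.3f",
           chosen$n_descriptors, chosen$r2, chosen$r2_cv)
      logf("model: %s", format_equation(chosen))
    } else {
      thr <- if (is.null(sel_cfg$threshold)) 0.85 else sel_cfg$threshold
      rep_ <- gbm_importance(xtr[, surviving, drop = FALSE], ytr,
                             gbm_params = if (is.null(sel_cfg$gbm_params))
                               list() else sel_cfg$gbm_params,
                             seed = stage_seed(config$seed, 3))
      selected <- select_cumulative(rep_, threshold = thr)
      write_importance(rep_, file.path(config$outdir, "importance.csv"))
      logf("GBM selection: %d descriptors reach cumulative importance %.2f",
           length(selected), thr)
      withCallingHandlers(
        correlation_matrix(xtr, selected),
        warning = function(w) {
          logf("note: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }

    stage <- "tune"
    tuned <- NULL
    kp <- config$svr
    svr_defaults <- list(C = 100, epsilon = 0.01, gamma = 1, p = 2L,
                         w = 0.5, b = 0.1)
    kp <- if (is.null(kp)) svr_defaults else utils::modifyList(svr_defaults, kp)
    rf_cfg <- do.call(rf_config, c(
      if (is.null(config$rf)) list() else config$rf,
      list(seed = stage_seed(config$seed, 5))))
    if (!is.null(config$tune) && isTRUE(config$tune$enabled)) {
      tc <- config$tune
      fam <- if (is.null(tc$family)) "mix_svr" else tc$family
      tuned <- tune_model(
        fam, xtr[, selected, drop = FALSE], ytr,
        n_folds = if (is.null(tc$n_folds)) 5 else tc$n_folds,
        epsilon = kp$epsilon,
        swarm_size = if (is.null(tc$swarm_size)) 15 else tc$swarm_size,
        ngen = if (is.null(tc$ngen)) 25 else tc$ngen,
        seed = stage_seed(config$seed, 4))
      write_pso_trace(tuned$trace, file.path(config$outdir, "pso_trace.csv"))
      logf("PSO tuning (%s): cv RMSE %.4f at %s", fam, tuned$cv_rmse,
           paste(names(tuned$par), signif(tuned$par, 4), sep = "=",
                 collapse = ", "))
      if (fam == "mix_svr") {
        kp <- utils::modifyList(kp, as.list(tuned$par))
      } else {
        rf_cfg <- rf_config(NT = tuned$par[["NT"]], MD = tuned$par[["MD"]],
                            MS = tuned$par[["MS"]], ML = tuned$par[["ML"]],
                            seed = stage_seed(config$seed, 5))
      }
    }

    stage <- "evaluate"
    report <- compare_models(
      x[, selected, drop = FALSE], y, split,
      models = unlist(config$models),
      kernel_params = kp[c("gamma", "p", "w", "b")],
      C = kp$C, epsilon = kp$epsilon, rf = rf_cfg)
    write_eval_report(report, config$outdir)
    logf("evaluation written; models: %s",
         paste(report$comparison$model, collapse = ", "))
    logf("done")
    invisible(list(selected = selected, tuned = tuned, report = report,
                   split = split,
                   artifacts = list.files(config$outdir, full.names = TRUE)))
  }, error = on_fail)
}
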