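#' Validate a run configuration
#'
#' A run configuration is a named list (typically read from a YAML file)
#' with optional sections `grid`, `irf`, `dataset`, `array`, `quant`,
#' `network`, `train`, `cmm` and top-level `seed` and `out_dir`. Every
#' section is validated against its module's constructor before any
#' computation; unknown sections or keys are rejected.
#'
#' @param config Named list, or path to a YAML file.
#' @return A validated list of class `run_config` with constructed
#'   component objects.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("grid", "irf", "dataset", "array", "quant", "train",
             "cmm", "seed", "out_dir")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  check_keys <- function(section, allowed) {
    bad <- setdiff(names(config[[section]]), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown keys in `%s`: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys("grid", c("n_bins", "bin_width_ns"))
  check_keys("irf", c("fwhm_ns", "peak_bin"))
  check_keys("dataset", c("n_samples", "val_fraction", "tau_range_ns",
                          "nt_range", "sigma_max_divisor", "seed"))
  check_keys("array", c("n_rows", "n_cols", "peak_jitter_span_ns",
                        "hot_pixel_fraction", "hot_pixel_rate_multiplier",
                        "dark_rate_per_bin"))
  check_keys("quant", c("w_bits", "a_bits"))
  check_keys("train", c("epochs", "batch_size", "learning_rate", "seed"))
  check_keys("cmm", c("window_start_bin", "window_end_bin"))

  seed <- as.integer(config$seed %||% 1L)
  grid <- do.call(sim_grid, config$grid %||% list())
  irf <- do.call(irf_spec, config$irf %||% list())
  ds_args <- config$dataset %||% list()
  if (is.null(ds_args$seed)) ds_args$seed <- seed
  dataset <- do.call(dataset_spec, lapply(ds_args, unlist))
  array <- do.call(array_spec, config$array %||% list())
  quant <- do.call(quant_scheme, config$quant %||% list())
  tr_args <- config$train %||% list()
  if (is.null(tr_args$seed)) tr_args$seed <- seed
  train <- do.call(train_config, tr_args)
  cmm_args <- config$cmm %||% list()
  cmm <- do.call(cmm_config, cmm_args)

  structure(list(grid = grid, irf = irf, dataset = dataset, array = array,
                 quant = quant, train = train, cmm = cmm, seed = seed,
                 out_dir = config$out_dir %||% "flimq_run"),
            class = "run_config")
}

#' Run the full simulation-training-evaluation pipeline
#'
#' Stages: (1) sample the synthetic dataset and write it out; (2) simulate
#' an IRF-only SPAD frame, calibrate it and write the calibration; (3) train
#' the QCNN and save the checkpoint; (4) sweep QCNN vs CMM accuracy and
#' precision over photon-count bins and write the results table. Every
#' artifact is stamped into a JSON run log together with the config hash
#' and seeds. A failing stage leaves earlier artifacts intact and reports
#' the stage name in the error.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param quiet Suppress stage messages? Default `FALSE`.
#' @return Invisibly, a list with the artifact paths, the trained fit and
#'   the evaluation table.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list(seed = cfg$seed,
              config_hash = config_hash(cfg),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  paths <- list()

  say("stage dataset: %d samples", cfg$dataset$n_samples)
  irf_curve <- make_irf(cfg$irf, cfg$grid)
  ds <- stage("dataset", sample_dataset(cfg$dataset, irf_curve, cfg$grid))
  paths$dataset <- file.path(cfg$out_dir, "dataset.csv")
  utils::write.csv(cbind(ds$meta, as.data.frame(ds$counts)), paths$dataset,
                   row.names = FALSE)

  say("stage calibration: %d x %d array", cfg$array$n_rows, cfg$array$n_cols)
  calib <- stage("calibration", {
    frame <- simulate_spad_frame(cfg$array, tau_ns = NULL,
                                 photons_per_frame = 100 * cfg$array$n_rows *
                                   cfg$array$n_cols,
                                 irf = cfg$irf, grid = cfg$grid,
                                 rng_seed = cfg$seed)
    calibrate_array(frame, reference_bin = cfg$irf$peak_bin)
  })
  paths$calibration <- file.path(cfg$out_dir, "calibration.csv")
  write_calibration(calib, paths$calibration)

  say("stage train: %d epochs", cfg$train$epochs)
  fit <- stage("train", {
    net <- build_network(network_spec(), cfg$quant, n_bins = cfg$grid$n_bins,
                         seed = cfg$train$seed)
    train_qcnn(net, ds, cfg$train)
  })
  paths$model <- file.path(cfg$out_dir, "model.rds")
  save_checkpoint(fit, paths$model)
  utils::write.csv(fit$history, file.path(cfg$out_dir, "loss_curves.csv"),
                   row.names = FALSE)

  say("stage evaluate: QCNN vs CMM sweep")
  sweep <- stage("evaluate", {
    irf_hist <- decay_histogram(irf_curve * 1e4, cfg$grid)
    test_spec <- cfg$dataset
    test_spec$seed <- cfg$seed + 1L
    sweep_vs_counts(
      list(CMM = cmm_estimator(cfg$cmm, irf_hist),
           QCNN = qcnn_estimator(fit)),
      test_spec = test_spec, grid = cfg$grid, irf = irf_curve)
  })
  paths$sweep <- file.path(cfg$out_dir, "sweep.csv")
  utils::write.csv(sweep, paths$sweep, row.names = FALSE)

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  log$artifacts <- paths
  paths$run_log <- file.path(cfg$out_dir, "run_log.json")
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, digits = NA)
  say("done: %s", cfg$out_dir)
  invisible(list(paths = paths, fit = fit, sweep = sweep, calibration = calib))
}

# deterministic hash of the configuration (djb2 over its deparsed form)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "cmm")]), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Save / load a QCNN checkpoint
#'
#' A checkpoint is a single RDS archive holding the trained network
#' (weights, batch-norm state), its architecture and quantization scheme,
#' the normalization rule and the training configuration and history.
#'
#' @param fit A `qcnn_fit` (or bare `qcnn`).
#' @param path Destination file.
#' @return `save_checkpoint()` invisibly returns `path`;
#'   `load_checkpoint()` returns the saved object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "qcnn_fit") || inherits(fit, "qcnn"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!(inherits(obj, "qcnn_fit") || inherits(obj, "qcnn"))) {
    stop("file is not a flimq checkpoint", call. = FALSE)
  }
  obj
}
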