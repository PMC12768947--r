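#' Default end-to-end pipeline configuration
#'
#' A plain (YAML-serializable) nested list collecting every tunable of the
#' benchmark: grid, simulator settings, dataset sizes (train 10000,
#' validation 2000, optimization 6000), network and training settings,
#' calibration concentrations, the four-test-set benchmark design, and a
#' seed for every stochastic stage.
#'
#' @param seed base seed; stage seeds are derived by small offsets.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    grid = list(start = 400, end = 2000, n_points = 660L),
    simulator = list(noise_sd = 0.01, max_shift = 2L,
                     background_scale = 0.1, zero_prob = 0.2,
                     min_frac = 0.01, scale_range = c(0.1, 10),
                     n_train = 10000L, n_validation = 2000L,
                     n_optimization = 6000L),
    training = list(max_epochs = 10L, batch_size = 64L,
                    learning_rate = 1e-3, patience = 8L),
    calibration = list(concs = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                       form = "hill"),
    benchmark = list(n_per_set = c(10L, 10L, 10L, 9L),
                     sparse_conc = 0.5, full_conc_range = c(0.1, 0.5)),
    seeds = list(simulate = seed, train = seed + 1L,
                 evaluate = seed + 2L)),
    class = "pipeline_config")
}

# small stable polynomial hash of the YAML rendering, for config/checkpoint
# pairing checks (kept in double-precision-safe integer range)
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

cfg_grid <- function(cfg)
  wavenumber_grid(cfg$grid$start, cfg$grid$end, cfg$grid$n_points)

cfg_noise <- function(cfg)
  noise_config(cfg$simulator$noise_sd, cfg$simulator$max_shift,
               cfg$simulator$background_scale)

#' Fit calibration curves for every target from its response model
#'
#' Emulates the single-analyte calibration experiment: each target is
#' measured (noise-free) at the configured concentration series and a
#' monotone curve is fitted to the resulting characteristic peak heights.
#'
#' @param responses named list of [response_model()].
#' @param concs calibration concentrations (uM).
#' @param form calibration form, see [fit_calibration_curve()].
#' @return Named list of [fit_calibration_curve()] objects.
#' @export
fit_calibration_set <- function(responses = default_response_models(),
                                concs = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                                form = "hill") {
  lapply(responses, function(r)
    fit_calibration_curve(concs, response_height(r, concs), form = form))
}

#' The four-test-set benchmark design
#'
#' Mirrors the evaluation design: two water backgrounds (drinking, river),
#' each with a full-mixture set (all five targets at varied concentrations)
#' and a sparse set (exactly 2 of 5 targets at equal concentrations).
#'
#' @param n_per_set sample counts for (drinking-full, drinking-sparse,
#'   river-full, river-sparse); the default totals 39.
#' @param sparse_conc concentration (uM) of each target in sparse samples.
#' @param full_conc_range per-target concentration range (uM) in full sets.
#' @return A list of four recipe lists.
#' @export
benchmark_design <- function(n_per_set = c(10L, 10L, 10L, 9L),
                             sparse_conc = 0.5,
                             full_conc_range = c(0.1, 0.5)) {
  stopifnot(length(n_per_set) == 4L, all(n_per_set >= 1L))
  list(
    list(name = "drinking-full", profile = "drinking", sparse = FALSE,
         n = n_per_set[1L], sparse_conc = sparse_conc,
         conc_range = full_conc_range),
    list(name = "drinking-sparse", profile = "drinking", sparse = TRUE,
         n = n_per_set[2L], sparse_conc = sparse_conc,
         conc_range = full_conc_range),
    list(name = "river-full", profile = "river", sparse = FALSE,
         n = n_per_set[3L], sparse_conc = sparse_conc,
         conc_range = full_conc_range),
    list(name = "river-sparse", profile = "river", sparse = TRUE,
         n = n_per_set[4L], sparse_conc = sparse_conc,
         conc_range = full_conc_range))
}

#' Simulate one benchmark test set with known ground truth
#'
#' Full samples contain all five targets with per-target concentrations
#' drawn uniformly over `recipe$conc_range`; sparse samples contain exactly
#' two targets at `recipe$sparse_conc` each. For every sample the raw
#' spectrum, its maximum, the true concentrations, and the self-consistent
#' regression labels (contribution fractions and normalization factor) are
#' recorded.
#'
#' @param recipe one element of [benchmark_design()].
#' @param refs reference [spectrum_set()].
#' @param responses named list of [response_model()].
#' @param cfg a [noise_config()].
#' @param seed RNG seed.
#' @return A list of class `test_set` with `x` (normalized spectra matrix),
#'   `raw_max`, `conc` (n x 5), `presence`, `labels` (n x 6 true regression
#'   labels) and the recipe name.
#' @export
simulate_test_set <- function(recipe, refs, responses,
                              cfg = noise_config(), seed = 1L) {
  set.seed(seed)
  targets <- names(refs$spectra)
  m <- length(targets)
  n <- recipe$n
  w <- refs$grid$n_points
  x <- matrix(0, n, w)
  conc <- matrix(0, n, m, dimnames = list(NULL, targets))
  labels <- matrix(0, n, m + 1L)
  raw_max <- numeric(n)
  for (i in seq_len(n)) {
    ci <- if (recipe$sparse) {
      v <- numeric(m)
      v[sample.int(m, 2L)] <- recipe$sparse_conc
      v
    } else {
      stats::runif(m, recipe$conc_range[1L], recipe$conc_range[2L])
    }
    sp <- simulate_measured_spectrum(ci, responses, refs, cfg,
                                     profile = recipe$profile)
    heights <- vapply(seq_len(m), function(j)
      response_height(responses[[targets[j]]], ci[j]), numeric(1))
    S <- sum(heights)
    raw_max[i] <- max(sp$intensities)
    x[i, ] <- sp$intensities / raw_max[i]
    conc[i, ] <- ci
    labels[i, ] <- c(heights / S, raw_max[i] / S)
  }
  structure(list(name = recipe$name, x = x, raw_max = raw_max, conc = conc,
                 presence = (conc > 0) + 0L, labels = labels,
                 grid = refs$grid, seed = seed), class = "test_set")
}

#' Evaluate trained models on benchmark test sets
#'
#' Runs the complete decision and quantification chain on each test set:
#' classifier scores -> thresholded presence calls -> Table-1-style metrics
#' and ROC; regressor 6-vectors -> concentrations via the calibration
#' curves -> concentration RMSE; predicted-spectrum reconstruction ->
#' spectral RMSE. With `oracle = TRUE` the true labels replace the model
#' predictions (a ceiling check of the conversion chain itself).
#'
#' @param classifier,regressor trained `sers_cnn` models (ignored when
#'   `oracle = TRUE`).
#' @param thresholds a [fit_thresholds()] object (oracle mode uses 0.5).
#' @param test_sets list of [simulate_test_set()] results.
#' @param refs reference [spectrum_set()].
#' @param curves calibration curves from [fit_calibration_set()].
#' @param oracle feed true labels instead of model predictions.
#' @return A list of class `evaluation_report` with one entry per test set
#'   plus `combined`.
#' @export
evaluate_models <- function(classifier, regressor, thresholds, test_sets,
                            refs, curves, oracle = FALSE) {
  names(test_sets) <- vapply(test_sets, `[[`, character(1), "name")
  per_set <- lapply(test_sets, function(ts) {
    n <- nrow(ts$x)
    if (oracle) {
      scores <- ts$presence + 0
      reg <- ts$labels
    } else {
      scores <- predict(classifier, ts$x)
      reg <- predict(regressor, ts$x)
    }
    calls <- if (oracle) ts$presence
             else classify(scores, thresholds)
    conc_pred <- matrix(0, n, ncol(ts$conc),
                        dimnames = dimnames(ts$conc))
    recon <- matrix(0, n, ncol(ts$x))
    for (i in seq_len(n)) {
      q <- contributions_to_concentrations(reg[i, ], ts$raw_max[i], curves)
      conc_pred[i, ] <- q$concentrations
      recon[i, ] <- reconstruct_predicted_spectrum(
        reg[i, ], refs, ts$raw_max[i])$intensities
    }
    list(name = ts$name, n = n,
         scores = scores, calls = calls, conc_pred = conc_pred,
         rmse_spectrum = rmse_spectrum(recon, ts$x),
         rmse_conc = rmse_conc(conc_pred, ts$conc))
  })
  names(per_set) <- vapply(test_sets, `[[`, character(1), "name")
  all_calls <- do.call(rbind, lapply(per_set, `[[`, "calls"))
  all_scores <- do.call(rbind, lapply(per_set, `[[`, "scores"))
  all_truth <- do.call(rbind, lapply(test_sets, `[[`, "presence"))
  all_conc_pred <- do.call(rbind, lapply(per_set, `[[`, "conc_pred"))
  all_conc <- do.call(rbind, lapply(test_sets, `[[`, "conc"))
  combined <- classification_report(all_calls, all_truth, all_scores)
  combined$rmse_conc <- rmse_conc(all_conc_pred, all_conc)
  combined$rmse_spectrum <- sqrt(stats::weighted.mean(
    vapply(per_set, function(s) s$rmse_spectrum^2, numeric(1)),
    vapply(per_set, `[[`, numeric(1), "n")))
  sets <- lapply(per_set, function(s) {
    rep <- classification_report(s$calls,
                                 test_sets[[s$name]]$presence, s$scores)
    list(name = s$name, n = s$n,
         rmse_spectrum = s$rmse_spectrum, rmse_conc = s$rmse_conc,
         micro_f1 = rep$micro$f1, percall_accuracy = rep$percall_accuracy,
         conc_pred = s$conc_pred, conc_true = test_sets[[s$name]]$conc)
  })
  structure(list(sets = sets, combined = combined, oracle = oracle),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s\n", if (x$oracle) " (oracle mode)" else ""))
  for (s in x$sets)
    cat(sprintf("  %-16s n=%2d  RMSE_spectrum %.4f  RMSE_conc %.4f uM  micro-F1 %s\n",
                s$name, s$n, s$rmse_spectrum, s$rmse_conc,
                ifelse(is.na(s$micro_f1), "NA", sprintf("%.3f", s$micro_f1))))
  cat(sprintf("  combined: micro-F1 %.3f  macro-F1 %.3f  per-call acc %.3f  subset acc %.3f\n",
              x$combined$micro$f1, x$combined$macro$f1,
              x$combined$percall_accuracy, x$combined$subset_accuracy))
  if (!is.null(x$combined$roc))
    cat(sprintf("  ROC-AUC: micro %.3f  macro %.3f\n",
                x$combined$roc$micro$auc, x$combined$roc$macro_auc))
  cat(sprintf("  combined RMSE_spectrum %.4f, RMSE_conc %.4f uM\n",
              x$combined$rmse_spectrum, x$combined$rmse_conc))
  invisible(x)
}

#' Run the full synthetic benchmark in memory
#'
#' simulate -> train -> evaluate with one call: generates the reference
#' library, training/validation datasets and the four test sets, trains the
#' classifier and regressor, fits validation thresholds and calibration
#' curves, and returns the evaluation report.
#'
#' @param cfg a [default_pipeline_config()]; sizes and seeds come from it.
#' @param oracle evaluate with true labels instead of trained models.
#' @param verbose print progress.
#' @return A list with the trained `classifier`, `regressor`, `thresholds`,
#'   `curves`, `test_sets` and the `report`.
#' @export
run_benchmark <- function(cfg = default_pipeline_config(), oracle = FALSE,
                          verbose = FALSE) {
  grid <- cfg_grid(cfg)
  refs <- default_reference_library(grid)
  responses <- default_response_models()
  noise <- cfg_noise(cfg)
  sim <- cfg$simulator
  say <- function(...) if (verbose) message(sprintf(...))
  classifier <- regressor <- thresholds <- NULL
  if (!oracle) {
    say("simulating training data (n=%d)", sim$n_train)
    tr <- generate_dataset(sim$n_train, "train", refs, noise,
                           seed = cfg$seeds$simulate,
                           zero_prob = sim$zero_prob,
                           min_frac = sim$min_frac,
                           scale_range = sim$scale_range)
    va <- generate_dataset(sim$n_validation, "validation", refs, noise,
                           seed = cfg$seeds$simulate + 1000L,
                           zero_prob = sim$zero_prob,
                           min_frac = sim$min_frac,
                           scale_range = sim$scale_range)
    tc <- training_config(cfg$training$max_epochs, cfg$training$batch_size,
                          cfg$training$learning_rate, cfg$training$patience,
                          seed = cfg$seeds$train)
    say("training classifier")
    classifier <- build_cnn(cnn_architecture(head = "classifier"),
                            grid$n_points, seed = cfg$seeds$train)
    classifier <- train_cnn(classifier, tr, va, tc, verbose = verbose)
    say("training regressor")
    regressor <- build_cnn(cnn_architecture(head = "regressor"),
                           grid$n_points, seed = cfg$seeds$train + 1L)
    regressor <- train_cnn(regressor, tr, va, tc, verbose = verbose)
    say("fitting validation thresholds")
    thresholds <- fit_thresholds(predict(classifier, va), va$presence)
  }
  curves <- fit_calibration_set(responses, cfg$calibration$concs,
                                cfg$calibration$form)
  design <- benchmark_design(cfg$benchmark$n_per_set,
                             cfg$benchmark$sparse_conc,
                             cfg$benchmark$full_conc_range)
  test_sets <- lapply(seq_along(design), function(i)
    simulate_test_set(design[[i]], refs, responses, noise,
                      seed = cfg$seeds$evaluate + i))
  say("evaluating on %d test sets", length(test_sets))
  report <- evaluate_models(classifier, regressor, thresholds, test_sets,
                            refs, curves, oracle = oracle)
  list(classifier = classifier, regressor = regressor,
       thresholds = thresholds, curves = curves, refs = refs,
       test_sets = test_sets, report = report, config = cfg)
}

# ---- file-based pipeline stages --------------------------------------------

#' Simulate and persist the benchmark datasets
#'
#' Writes the reference library (CSV + manifest), the train / validation /
#' optimization datasets (RDS container plus CSV label tables), the config
#' snapshot (YAML) and its hash to `out_dir`. Refuses to overwrite existing
#' outputs unless `force = TRUE`; reruns with the same config are
#' bit-identical.
#'
#' @param cfg a [default_pipeline_config()].
#' @param out_dir output directory.
#' @param force overwrite existing outputs.
#' @return Invisibly, `out_dir`.
#' @export
pipeline_simulate <- function(cfg = default_pipeline_config(), out_dir,
                              force = FALSE) {
  marker <- file.path(out_dir, "config.yaml")
  if (file.exists(marker) && !force)
    stop("pipeline_simulate: outputs exist in ", out_dir,
         " (use force = TRUE to overwrite)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cfg_grid(cfg)
  refs <- default_reference_library(grid)
  write_spectrum_set(refs, file.path(out_dir, "references"))
  noise <- cfg_noise(cfg)
  sim <- cfg$simulator
  sizes <- c(train = sim$n_train, validation = sim$n_validation,
             optimization = sim$n_optimization)
  offs <- c(train = 0L, validation = 1000L, optimization = 2000L)
  for (role in names(sizes)) {
    ds <- generate_dataset(sizes[[role]], role, refs, noise,
                           seed = cfg$seeds$simulate + offs[[role]],
                           zero_prob = sim$zero_prob,
                           min_frac = sim$min_frac,
                           scale_range = sim$scale_range)
    saveRDS(ds, file.path(out_dir, paste0(role, ".rds")))
    utils::write.csv(
      data.frame(ds$contributions, norm_factor = ds$norm_factor,
                 raw_max = ds$raw_max),
      file.path(out_dir, paste0(role, "_labels.csv")), row.names = FALSE)
  }
  yaml::write_yaml(unclass(cfg), marker)
  writeLines(config_hash(cfg), file.path(out_dir, "config.hash"))
  invisible(out_dir)
}

#' Train both models from persisted datasets
#'
#' Loads the datasets written by [pipeline_simulate()], trains the
#' classifier and regressor, fits validation thresholds, and writes the two
#' checkpoints (with the architecture embedded as JSON metadata), training
#' histories (CSV) and thresholds (JSON).
#'
#' @param cfg the same config used for simulation.
#' @param data_dir directory written by [pipeline_simulate()].
#' @param out_dir output directory (defaults to `data_dir`).
#' @param verbose print per-epoch losses.
#' @return Invisibly, a list with both trained models and the thresholds.
#' @export
pipeline_train <- function(cfg = default_pipeline_config(), data_dir,
                           out_dir = data_dir, verbose = FALSE) {
  tr_path <- file.path(data_dir, "train.rds")
  va_path <- file.path(data_dir, "validation.rds")
  if (!file.exists(tr_path) || !file.exists(va_path))
    stop("pipeline_train: datasets not found in ", data_dir,
         " (run pipeline_simulate first)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- readRDS(tr_path); va <- readRDS(va_path)
  tc <- training_config(cfg$training$max_epochs, cfg$training$batch_size,
                        cfg$training$learning_rate, cfg$training$patience,
                        seed = cfg$seeds$train)
  out <- list()
  for (head in c("classifier", "regressor")) {
    m <- build_cnn(cnn_architecture(head = head), ncol(tr$x),
                   seed = cfg$seeds$train + (head == "regressor"))
    m <- train_cnn(m, tr, va, tc, verbose = verbose)
    save_cnn(m, file.path(out_dir, paste0(head, ".rds")),
             config_hash = config_hash(cfg))
    utils::write.csv(m$history,
                     file.path(out_dir, paste0(head, "_history.csv")),
                     row.names = FALSE)
    out[[head]] <- m
  }
  thr <- fit_thresholds(predict(out$classifier, va), va$presence)
  jsonlite::write_json(list(thresholds = thr$thresholds,
                            geometric_means = thr$geometric_means,
                            targets = thr$targets),
                       file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  out$thresholds <- thr
  invisible(out)
}

#' Evaluate persisted checkpoints on the synthetic benchmark
#'
#' Loads the checkpoints written by [pipeline_train()] (verifying the
#' config hash), simulates the four test sets, and writes per-set and
#' combined report JSON files.
#'
#' @param cfg the same config used upstream.
#' @param model_dir directory with `classifier.rds`, `regressor.rds`,
#'   `thresholds.json`.
#' @param out_dir report output directory.
#' @param oracle evaluate with true labels (ceiling check).
#' @return Invisibly, the [evaluate_models()] report.
#' @export
pipeline_evaluate <- function(cfg = default_pipeline_config(), model_dir,
                              out_dir = model_dir, oracle = FALSE) {
  classifier <- regressor <- thresholds <- NULL
  if (!oracle) {
    cp <- file.path(model_dir, "classifier.rds")
    rp <- file.path(model_dir, "regressor.rds")
    if (!file.exists(cp) || !file.exists(rp))
      stop("pipeline_evaluate: checkpoints not found in ", model_dir,
           " (run pipeline_train first)")
    classifier <- load_cnn(cp)
    regressor <- load_cnn(rp)
    h <- config_hash(cfg)
    for (m in list(classifier, regressor))
      if (!is.null(attr(m, "config_hash")) && attr(m, "config_hash") != h)
        stop("pipeline_evaluate: checkpoint was trained under a different config")
    thr <- jsonlite::read_json(file.path(model_dir, "thresholds.json"),
                               simplifyVector = TRUE)
    thresholds <- structure(list(thresholds = thr$thresholds,
                                 geometric_means = thr$geometric_means,
                                 targets = thr$targets),
                            class = "threshold_set")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cfg_grid(cfg)
  refs <- default_reference_library(grid)
  responses <- default_response_models()
  curves <- fit_calibration_set(responses, cfg$calibration$concs,
                                cfg$calibration$form)
  design <- benchmark_design(cfg$benchmark$n_per_set,
                             cfg$benchmark$sparse_conc,
                             cfg$benchmark$full_conc_range)
  test_sets <- lapply(seq_along(design), function(i)
    simulate_test_set(design[[i]], refs, responses, cfg_noise(cfg),
                      seed = cfg$seeds$evaluate + i))
  report <- evaluate_models(classifier, regressor, thresholds, test_sets,
                            refs, curves, oracle = oracle)
  summary_json <- list(
    config_hash = config_hash(cfg),
    oracle = oracle,
    sets = lapply(report$sets, function(s)
      list(name = s$name, n = s$n, rmse_spectrum = s$rmse_spectrum,
           rmse_conc = s$rmse_conc, micro_f1 = s$micro_f1)),
    combined = list(micro_f1 = report$combined$micro$f1,
                    macro_f1 = report$combined$macro$f1,
                    micro_precision = report$combined$micro$precision,
                    percall_accuracy = report$combined$percall_accuracy,
                    subset_accuracy = report$combined$subset_accuracy,
                    rmse_spectrum = report$combined$rmse_spectrum,
                    rmse_conc = report$combined$rmse_conc,
                    auc_micro = if (!is.null(report$combined$roc))
                      report$combined$roc$micro$auc,
                    auc_macro = if (!is.null(report$combined$roc))
                      report$combined$roc$macro_auc))
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Save / load a CNN checkpoint
#'
#' Single-file weight store with the architecture embedded as JSON metadata
#' (and, optionally, the pipeline config hash for pairing checks).
#'
#' @param model a `sers_cnn`.
#' @param path checkpoint path.
#' @param config_hash optional hash string recorded with the checkpoint.
#' @return `save_cnn` invisibly returns `path`; `load_cnn` returns the
#'   restored `sers_cnn`.
#' @export
save_cnn <- function(model, path, config_hash = NULL) {
  stopifnot(inherits(model, "sers_cnn"))
  meta <- jsonlite::toJSON(list(
    head = model$architecture$head,
    conv_blocks = lapply(model$architecture$conv_blocks, unlist),
    dense_units = model$architecture$dense_units,
    dropout = model$architecture$dropout,
    input_length = model$input_length, seed = model$seed),
    auto_unbox = TRUE)
  saveRDS(list(model = model, meta = as.character(meta),
               config_hash = config_hash), path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- readRDS(path)
  m <- obj$model
  attr(m, "config_hash") <- obj$config_hash
  attr(m, "meta") <- obj$meta
  m
}
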