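#' Assemble an experiment configuration
#'
#' Bundles the dataset source, model parameters, pruning method, and
#' seeding for a full experiment.  One global seed fans out to
#' per-component streams (data generation, weight initialization plus
#' simulation) so components can be varied independently.
#'
#' @param dataset A list: either `list(type = "synthetic", spec =
#'   synthetic_spec(), n_train =, n_test =)` or `list(type = "idx",
#'   images =, labels =, test_images =, test_labels =)` with file paths.
#' @param arch,neuron,neuron_inh,plasticity Model configuration.
#' @param prune A [prune_config()].
#' @param seed Global seed.
#' @param monitor_window Dynamics window (images).
#' @param n_assign Assignment subset size (`NULL` = full training set).
#' @param epochs Training passes.
#' @return A list of class `experiment_config` (validated).
#' @export
experiment_config <- function(dataset = list(type = "synthetic",
                                             spec = synthetic_spec(),
                                             n_train = 3000, n_test = 300),
                              arch = NULL,
                              neuron = neuron_params(),
                              neuron_inh = inhibitory_params(),
                              plasticity = plasticity_params(),
                              prune = prune_config("none"),
                              seed = 1,
                              monitor_window = 5000,
                              n_assign = NULL,
                              epochs = 1) {
  cfg <- structure(list(dataset = dataset, arch = arch, neuron = neuron,
                        neuron_inh = neuron_inh, plasticity = plasticity,
                        prune = prune, seed = as.integer(seed),
                        monitor_window = monitor_window,
                        n_assign = n_assign, epochs = epochs),
                   class = "experiment_config")
  validate_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' Checks every module's preconditions before any compute and fails with
#' a structured message naming the offending field.
#'
#' @param config An [experiment_config()].
#' @return The config, invisibly.
#' @export
validate_config <- function(config) {
  fail <- function(field, why)
    stop(sprintf("invalid config: %s — %s", field, why), call. = FALSE)
  ds <- config$dataset
  if (is.null(ds$type) || !ds$type %in% c("synthetic", "idx"))
    fail("dataset$type", "must be 'synthetic' or 'idx'")
  if (ds$type == "synthetic") {
    if (!inherits(ds$spec, "synthetic_spec"))
      fail("dataset$spec", "must be a synthetic_spec")
    if (is.null(ds$n_train) || ds$n_train < 1)
      fail("dataset$n_train", "must be >= 1")
  } else {
    for (f in c("images", "labels", "test_images", "test_labels"))
      if (is.null(ds[[f]]) || !file.exists(ds[[f]]))
        fail(paste0("dataset$", f), "file missing")
  }
  if (!is.null(config$arch) && !inherits(config$arch, "arch_config"))
    fail("arch", "must be an arch_config")
  if (!inherits(config$neuron, "neuron_params"))
    fail("neuron", "must be neuron_params")
  if (!inherits(config$neuron_inh, "neuron_params"))
    fail("neuron_inh", "must be neuron_params")
  if (!inherits(config$plasticity, "plasticity_params"))
    fail("plasticity", "must be plasticity_params")
  if (!inherits(config$prune, "prune_config"))
    fail("prune", "must be a prune_config")
  if (!is.null(config$arch) &&
      config$arch$dt > min(config$neuron$tau_ge, config$neuron$tau_gi))
    fail("arch$dt", "must not exceed the conductance time constants")
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    fail("seed", "must be a single integer")
  if (config$monitor_window < 1) fail("monitor_window", "must be >= 1")
  invisible(config)
}

#' Seed fan-out for an experiment
#'
#' @param seed Global seed (small integer).
#' @return List of derived per-component seeds (`data`, `model`, `eval`),
#'   all below 2^31.
#' @export
seed_streams <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(data = base * 2L + 11L, model = base * 2L + 101L,
       eval = base * 2L + 1009L)
}

load_dataset <- function(config) {
  ds <- config$dataset
  seeds <- seed_streams(config$seed)
  if (ds$type == "synthetic") {
    spec <- ds$spec
    spec$seed <- seeds$data
    make_synthetic(spec, ds$n_train,
                   if (is.null(ds$n_test)) 0 else ds$n_test)
  } else {
    list(train = read_idx(ds$images, ds$labels, "train"),
         test = read_idx(ds$test_images, ds$test_labels, "test"))
  }
}

default_arch <- function(config, data) {
  if (!is.null(config$arch)) return(config$arch)
  d <- dim(data$train$images)
  arch_config(grid_h = d[2], grid_w = d[3], n_exc = 100)
}

run_id <- function(config) {
  # small polynomial hash of the serialized config, for a stable run id
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_run_metadata <- function(config, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(run_id = run_id(config), seed = config$seed,
               dataset_type = config$dataset$type,
               prune_method = config$prune$method,
               wth0 = config$prune$wth0,
               config = utils::capture.output(utils::str(config)))
  jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE)
  invisible(meta)
}

#' Train a network from an experiment configuration
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory for CSV logs (dynamics, prune
#'   log) and the resolved run metadata.
#' @param assign Run the label-assignment pass.
#' @return List with the `fit` and the loaded `data`.
#' @export
run_train <- function(config, out_dir = NULL, assign = TRUE) {
  validate_config(config)
  data <- load_dataset(config)
  arch <- default_arch(config, data)
  seeds <- seed_streams(config$seed)
  fit <- train_snn(data$train, arch = arch, neuron = config$neuron,
                   neuron_inh = config$neuron_inh,
                   plasticity = config$plasticity, prune = config$prune,
                   seed = seeds$model, epochs = config$epochs,
                   monitor_window = config$monitor_window,
                   assign = assign, n_assign = config$n_assign)
  if (!is.null(out_dir)) {
    write_run_metadata(config, out_dir)
    write_results(fit$dynamics, file.path(out_dir, "dynamics.csv"))
    if (nrow(fit$prune_log) > 0)
      write_results(fit$prune_log, file.path(out_dir, "prune_log.csv"))
  }
  list(fit = fit, data = data)
}

#' Evaluate a trained network on the configured test set
#'
#' @param config The experiment configuration.
#' @param fit An `snn_wta` fit (from [run_train()]).
#' @param data Optional pre-loaded dataset (reloaded from the config
#'   otherwise).
#' @return Test accuracy (fraction correct).
#' @export
run_evaluate <- function(config, fit, data = NULL) {
  if (is.null(data)) data <- load_dataset(config)
  seeds <- seed_streams(config$seed)
  evaluate_accuracy(fit, data$test, seed = seeds$eval)
}

#' Sweep initial pruning thresholds and report accuracy vs connectivity
#'
#' Reproduces the threshold-sweep protocol: one unpruned baseline run,
#' then one pruned run per `wth0`, all with the same seed and data;
#' reports connectivity, accuracy, accuracy loss, SOPs/image, normalized
#' reductions, and the figure of merit per threshold.
#'
#' @param config Base configuration (its `prune` supplies the method and
#'   adaptation settings).
#' @param wth0_values Initial thresholds to sweep.
#' @param out_dir Optional output directory for the CSV table.
#' @return Data frame with one row per threshold.
#' @export
run_prune_sweep <- function(config, wth0_values, out_dir = NULL) {
  validate_config(config)
  base_cfg <- config
  base_cfg$prune <- prune_config("none")
  base <- run_train(base_cfg)
  acc_base <- run_evaluate(base_cfg, base$fit, base$data)
  rows <- lapply(wth0_values, function(w0) {
    cfg <- config
    cfg$prune <- replace_wth0(config$prune, w0)
    run <- run_train(cfg)
    acc <- run_evaluate(cfg, run$fit, run$data)
    rep <- fom_report(run$fit, base$fit, acc, acc_base)
    cbind(data.frame(wth0 = w0, method = cfg$prune$method), rep)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(out, file.path(out_dir, "prune_sweep.csv"))
  }
  out
}

replace_wth0 <- function(prune, wth0) {
  prune_config(prune$method, wth0 = wth0,
               time_kind = prune$schedule$kind,
               time_factor = if (prune$method %in% c("APT", "APTN"))
                 prune$schedule$factor else 1.3,
               neuron_kind = prune$neuron_kind,
               neuron_factor = if (prune$method %in% c("APN", "APTN"))
                 prune$neuron_factor else 1.15,
               SI = prune$SI, t_m = prune$t_m, batch = prune$batch,
               w_max = prune$w_max)
}

#' Overhead report for the configured architecture
#'
#' @param config The experiment configuration (grid and `n_exc` set the
#'   plastic projection size).
#' @param model An [overhead_model()].
#' @param sops_per_image Training SOPs/image used for the energy
#'   comparison.
#' @return List with the per-batch cycle/op table, per-image averages,
#'   energy estimates, and the NAND gate ratio.
#' @export
run_overhead <- function(config, model = overhead_model(),
                         sops_per_image = 96099) {
  arch <- config$arch
  if (is.null(arch)) arch <- arch_config()
  oh <- estimate_pruning_overhead(arch$n_input, arch$n_exc, model,
                                  config$prune$batch)
  en <- estimate_energy(sops_per_image, oh$ops_per_image, model)
  list(overhead = oh, energy = en, gate_ratio = gate_ratio(model),
       brams = c(prune = model$brams_prune, snn = model$brams_snn))
}

#' Accuracy as a function of the pruning start point
#'
#' Runs the configured pruning method with different numbers of
#' pre-pruning training images and reports accuracy and connectivity for
#' each.
#'
#' @param config Base configuration.
#' @param t_m_values Pre-pruning image counts to scan.
#' @param out_dir Optional output directory.
#' @return Data frame with `t_m`, `connectivity`, `accuracy`.
#' @export
run_prestart_scan <- function(config, t_m_values, out_dir = NULL) {
  rows <- lapply(t_m_values, function(tm) {
    cfg <- config
    p <- config$prune
    cfg$prune <- prune_config(p$method, wth0 = p$wth0,
                              time_kind = p$schedule$kind,
                              time_factor = p$schedule$factor,
                              neuron_kind = p$neuron_kind,
                              neuron_factor = p$neuron_factor,
                              SI = p$SI, t_m = tm, batch = p$batch,
                              w_max = p$w_max)
    run <- run_train(cfg)
    data.frame(t_m = tm, connectivity = connectivity(run$fit),
               accuracy = run_evaluate(cfg, run$fit, run$data))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(out, file.path(out_dir, "prestart_scan.csv"))
  }
  out
}

#' Find the initial threshold reaching a target connectivity
#'
#' Bisects `wth0` (training-only runs, no assignment pass) until the
#' final connectivity is within `tol` of the target.  Connectivity is
#' non-increasing in `wth0`, which makes bisection well-posed.
#'
#' @param config Base configuration (the prune method to calibrate).
#' @param target Target final connectivity (fraction).
#' @param lower,upper Bracketing thresholds.
#' @param tol Acceptable |connectivity - target|.
#' @param max_iter Bisection iterations.
#' @return List with `wth0`, the achieved `connectivity`, and the `fit`
#'   of the final run.
#' @export
find_wth0_for_connectivity <- function(config, target, lower = 0,
                                       upper = NULL, tol = 0.02,
                                       max_iter = 8) {
  if (is.null(upper)) upper = config$prune$w_max * 0.9
  conn_at <- function(w0) {
    cfg <- config
    cfg$prune <- replace_wth0(config$prune, w0)
    run <- suppressWarnings(run_train(cfg, assign = FALSE))
    list(conn = connectivity(run$fit), fit = run$fit)
  }
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    res <- conn_at(mid)
    best <- list(wth0 = mid, connectivity = res$conn, fit = res$fit)
    if (abs(res$conn - target) <= tol) break
    if (res$conn > target) lower <- mid else upper <- mid
  }
  best
}
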