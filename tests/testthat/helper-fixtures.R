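# Shared desk-scale fixtures.  Heavy trained networks are built once per
# test run and cached, so several tests can interrogate the same fit.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

desk_arch <- function(n_exc = 30) arch_config(16, 16, n_exc = n_exc)

desk_data <- function(seed = 1001, n_train = 3000, n_test = 300) {
  fixture(sprintf("data_%d_%d_%d", seed, n_train, n_test), function()
    make_synthetic(synthetic_spec(seed = seed), n_train, n_test))
}

# standard desk-scale study conditions: 30 excitatory neurons, 3 classes,
# 3,000 training images; pruning starts at 1,500 with 250-image batches
desk_prune <- function(method, wth0, ...) {
  prune_config(method, wth0 = wth0, t_m = 1500, batch = 250, ...)
}

desk_fit <- function(key, prune = prune_config("none"), seed = 7,
                     data = desk_data(), n_assign = NULL) {
  fixture(key, function()
    suppressWarnings(train_snn(data$train, arch = desk_arch(),
                               prune = prune, monitor_window = 500,
                               seed = seed, n_assign = n_assign)))
}

baseline_fit <- function() desk_fit("baseline")

# a deterministic single-step drive: p = 1 for the chosen units
one_step_net <- function(n_in = 4, n_exc = 3, w = NULL, status = 0L,
                         present_ms = 0.5, rest_ms = 0, seed = 42) {
  arch <- arch_config(grid_h = 1, grid_w = n_in, n_exc = n_exc,
                      present_ms = present_ms, rest_ms = rest_ms,
                      max_rate_hz = 2000)
  set.seed(seed)
  net <- new_snn_network(arch)
  if (!is.null(w)) net$w <- matrix(w, n_in, n_exc)
  if (length(status) > 1 || status != 0L)
    net$status <- matrix(as.integer(status), n_in, n_exc)
  net
}
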