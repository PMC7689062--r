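#' Create a fresh synaptic-operation ledger
#'
#' Counters of weight-accumulation and STDP-update events, kept per phase
#' (training, label assignment, inference) and per projection: the plastic
#' input-to-excitatory projection drives the `*_accum` and `train_stdp_*`
#' counters, while fixed lateral events are tallied separately under
#' `lateral_ei_*` (excitatory to inhibitory) and `lateral_ie_*`.
#'
#' @return An environment of class `sop_ledger` with all counters at zero.
#' @export
new_sop_ledger <- function() {
  e <- new.env(parent = emptyenv())
  for (nm in c("train_accum", "assign_accum", "infer_accum",
               "train_stdp_pre", "train_stdp_post",
               "lateral_ei_train", "lateral_ei_assign", "lateral_ei_infer",
               "lateral_ie_train", "lateral_ie_assign", "lateral_ie_infer",
               "images_train", "images_assign", "images_infer"))
    assign(nm, 0, envir = e)
  class(e) <- "sop_ledger"
  e
}

#' Record synaptic operations in a ledger
#'
#' One accumulation SOP is counted per presynaptic spike delivered across
#' each non-removed synapse; one STDP SOP per performed weight update on
#' an active synapse (pre- and post-triggered updates are counted
#' separately, and a clipped zero-magnitude update still counts).  Frozen
#' synapses accumulate but never incur STDP SOPs; removed synapses incur
#' neither.  The simulation engine maintains these counters itself; this
#' function is the manual interface used for instrumentation and testing.
#'
#' @param ledger A [new_sop_ledger()] environment.
#' @param kind `"accum"` or `"stdp"`.
#' @param phase `"train"`, `"assign"`, or `"infer"`.
#' @param count Non-negative number of operations.
#' @param trigger For `kind = "stdp"`, `"pre"` or `"post"`.
#' @return The ledger, invisibly.
#' @export
record_sop <- function(ledger, kind = c("accum", "stdp"),
                       phase = c("train", "assign", "infer"),
                       count = 1, trigger = c("pre", "post")) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  if (count < 0) stop("record_sop: count must be >= 0")
  if (kind == "accum") {
    nm <- paste0(phase, "_accum")
  } else {
    if (phase != "train")
      stop("record_sop: STDP operations only occur during training")
    nm <- paste0("train_stdp_", match.arg(trigger))
  }
  assign(nm, get(nm, envir = ledger) + count, envir = ledger)
  invisible(ledger)
}

#' Snapshot a ledger as a named list
#'
#' @param ledger A `sop_ledger` environment, `snn_network`, or `snn_wta`
#'   fit.
#' @return Named list of counter values.
#' @export
ledger_summary <- function(ledger) {
  if (inherits(ledger, "snn_wta")) ledger <- ledger$network$ledger
  if (inherits(ledger, "snn_network")) ledger <- ledger$ledger
  mget(ls(ledger), envir = ledger)
}

#' Build an initialized WTA spiking network
#'
#' Synaptic weights of the plastic projection are initialized uniformly on
#' `[0, 0.3 * w_max]`; all synapses start active; all neurons start at
#' rest with zero conductances, traces, and adaptive thresholds.  The
#' caller controls the RNG state (seed) used for initialization.
#'
#' @param arch An [arch_config()].
#' @param neuron Excitatory [neuron_params()].
#' @param neuron_inh Inhibitory [neuron_params()]; defaults to
#'   [inhibitory_params()].
#' @param plasticity A [plasticity_params()].
#' @return An environment of class `snn_network`.
#' @export
new_snn_network <- function(arch = arch_config(),
                            neuron = neuron_params(),
                            neuron_inh = inhibitory_params(),
                            plasticity = plasticity_params()) {
  if (arch$dt > min(neuron$tau_ge, neuron$tau_gi))
    stop("new_snn_network: dt must not exceed the conductance time constants")
  n_in <- arch$n_input
  n_exc <- arch$n_exc
  net <- new.env(parent = emptyenv())
  net$arch <- arch
  net$neuron <- neuron
  net$neuron_inh <- neuron_inh
  net$plasticity <- plasticity
  net$w <- matrix(runif(n_in * n_exc, 0, 0.3 * plasticity$w_max),
                  n_in, n_exc)
  net$status <- matrix(0L, n_in, n_exc)
  net$v_exc <- rep(neuron$v_r, n_exc)
  net$ge_exc <- numeric(n_exc)
  net$gi_exc <- numeric(n_exc)
  net$theta <- numeric(n_exc)
  net$refrac_exc <- numeric(n_exc)
  net$v_inh <- rep(neuron_inh$v_r, n_exc)
  net$ge_inh <- numeric(n_exc)
  net$refrac_inh <- numeric(n_exc)
  net$x <- numeric(n_in)
  net$y1 <- numeric(n_exc)
  net$y2 <- numeric(n_exc)
  net$prev_exc <- integer(n_exc)
  net$prev_inh <- integer(n_exc)
  net$ledger <- new_sop_ledger()
  net$images_seen <- 0
  class(net) <- "snn_network"
  net
}

#' Explicit winner-take-all connectivity matrices
#'
#' Returns the fixed lateral weight matrices implied by the one-to-one
#' excitatory-to-inhibitory wiring and the all-but-self
#' inhibitory-to-excitatory wiring.  The simulation engine exploits the
#' structure directly; these matrices document and test it.
#'
#' @param n_exc Number of excitatory (= inhibitory) neurons.
#' @param w_exc_inh One-to-one weight.
#' @param w_inh_exc All-but-self weight.
#' @return List with `exc_inh` (diagonal) and `inh_exc` (zero diagonal,
#'   shared off-diagonal value).
#' @export
wta_weight_matrices <- function(n_exc, w_exc_inh = 10.4, w_inh_exc = 17.0) {
  list(exc_inh = diag(w_exc_inh, n_exc),
       inh_exc = matrix(w_inh_exc, n_exc, n_exc) - diag(w_inh_exc, n_exc))
}

#' Poisson rate coding of an intensity image
#'
#' Each input unit fires independently per time step with probability
#' `rate_j * dt`, where `rate_j = (intensity_j / 255) * max_rate`.
#'
#' @param image Numeric vector or matrix of intensities in `[0, 255]`.
#' @param duration Encoding duration (ms).
#' @param max_rate Firing rate (Hz) at intensity 255.
#' @param dt Time step (ms).
#' @return Binary matrix with one row per time step and one column per
#'   input unit.
#' @export
#' @examples
#' s <- encode_poisson(c(0, 255), duration = 10, max_rate = 100, dt = 0.5)
#' colSums(s)[1]  # zero-intensity pixel never spikes
encode_poisson <- function(image, duration, max_rate, dt = 0.5) {
  intens <- as.numeric(image)
  if (anyNA(intens) || any(intens < 0 | intens > 255))
    stop("encode_poisson: intensities must be in [0, 255]")
  n_steps <- as.integer(round(duration / dt))
  p <- pmin(1, (intens / 255) * max_rate * dt / 1000)
  m <- matrix(runif(n_steps * length(p)), n_steps, length(p))
  (m < matrix(p, n_steps, length(p), byrow = TRUE)) * 1L
}

spike_probabilities <- function(image, arch) {
  intens <- as.numeric(image)
  if (anyNA(intens) || any(intens < 0 | intens > 255))
    stop("present_image: intensities must be in [0, 255]")
  if (length(intens) != arch$n_input)
    stop("present_image: image size does not match the input grid")
  pmin(1, (intens / 255) * arch$max_rate_hz * arch$dt / 1000)
}

#' Present one image to the network
#'
#' Simulates `present_ms` of Poisson-coded input followed by `rest_ms` of
#' silence.  Each excitatory spike drives its one-to-one inhibitory
#' partner; each inhibitory spike inhibits all excitatory neurons except
#' its source.  With `plastic = TRUE` the triplet STDP rule and threshold
#' adaptation run; otherwise weights, adaptive thresholds, and learning
#' traces are untouched.  Synaptic operations are recorded in the
#' network's ledger under the given phase.
#'
#' @param net An [new_snn_network()] environment (updated in place).
#' @param image Intensities in `[0, 255]`, length `n_input`.
#' @param plastic Whether STDP and threshold adaptation are enabled.
#' @param phase Ledger phase; defaults to `"train"` when plastic and
#'   `"infer"` otherwise.
#' @return A list of class `spike_record` with per-excitatory-neuron
#'   spike `counts`, the input spike total, and weight-change summaries
#'   (`dw_n`, `dw_sum`, `dw_sumsq`).
#' @export
present_image <- function(net, image, plastic = TRUE,
                          phase = if (plastic) "train" else "infer") {
  phase <- match.arg(phase, c("train", "assign", "infer"))
  arch <- net$arch
  p <- spike_probabilities(image, arch)
  n_present <- as.integer(round(arch$present_ms / arch$dt))
  n_rest <- as.integer(round(arch$rest_ms / arch$dt))
  out <- sim_present_cpp(net, p, n_present, n_rest, arch$dt,
                         unclass(net$neuron), unclass(net$neuron_inh),
                         unclass(net$plasticity),
                         arch$w_exc_inh, arch$w_inh_exc,
                         plastic, plastic,
                         match(phase, c("train", "assign", "infer")) - 1L,
                         net$plasticity$norm_frac * arch$n_input *
                           net$plasticity$w_max)
  net$images_seen <- net$images_seen + 1
  structure(out, class = "spike_record")
}

#' Reset the transient state of a network
#'
#' Clears membrane potentials, conductances, traces, and pending lateral
#' spikes without touching weights, synapse statuses, or adaptive
#' thresholds.  Used between training and evaluation passes.
#'
#' @param net An `snn_network`.
#' @return The network, invisibly.
#' @export
reset_transient_state <- function(net) {
  n_exc <- net$arch$n_exc
  net$v_exc <- rep(net$neuron$v_r, n_exc)
  net$ge_exc <- numeric(n_exc)
  net$gi_exc <- numeric(n_exc)
  net$refrac_exc <- numeric(n_exc)
  net$v_inh <- rep(net$neuron_inh$v_r, n_exc)
  net$ge_inh <- numeric(n_exc)
  net$refrac_inh <- numeric(n_exc)
  net$x <- numeric(net$arch$n_input)
  net$y1 <- numeric(n_exc)
  net$y2 <- numeric(n_exc)
  net$prev_exc <- integer(n_exc)
  net$prev_inh <- integer(n_exc)
  invisible(net)
}
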