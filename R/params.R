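#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of the conductance-based LIF model
#' \deqn{\tau_m dv/dt = (v_r - v) - g_e (v - E_{exc}) - g_i (v - E_{inh}),}
#' with an adaptive firing threshold: a neuron spikes when
#' `v >= v_th + theta`, after which `v` is reset to `v_r` and `theta` is
#' incremented by `theta_plus`; `theta` decays exponentially with
#' `tau_theta`.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_r Resting (and reset) potential (mV).
#' @param v_th Base firing threshold (mV).
#' @param E_exc,E_inh Excitatory and inhibitory reversal potentials (mV).
#' @param tau_ge,tau_gi Excitatory and inhibitory conductance time
#'   constants (ms).
#' @param theta_plus Threshold adaptation increment per spike (mV).
#' @param tau_theta Adaptive-threshold decay time constant (ms); large
#'   values make the homeostatic threshold quasi-static within one image.
#' @param t_refrac Absolute refractory period (ms).
#' @return A list of class `neuron_params`.
#' @export
#' @examples
#' np <- neuron_params()
#' np$tau_m
neuron_params <- function(tau_m = 100, v_r = -60, v_th = -50,
                          E_exc = 0, E_inh = -100,
                          tau_ge = 1, tau_gi = 2,
                          theta_plus = 0.01, tau_theta = 1e5,
                          t_refrac = 0) {
  p <- list(tau_m = tau_m, v_r = v_r, v_th = v_th,
            E_exc = E_exc, E_inh = E_inh,
            tau_ge = tau_ge, tau_gi = tau_gi,
            theta_plus = theta_plus, tau_theta = tau_theta,
            t_refrac = t_refrac)
  stopifnot(vapply(p, is.numeric, TRUE), vapply(p, length, 1L) == 1L)
  if (!all(is.finite(unlist(p)))) stop("neuron_params: non-finite value")
  if (tau_m <= 0 || tau_ge <= 0 || tau_gi <= 0 || tau_theta <= 0)
    stop("neuron_params: all time constants must be > 0")
  if (v_r >= v_th) stop("neuron_params: v_r must be below v_th")
  if (E_inh >= v_r) stop("neuron_params: E_inh must be below v_r")
  if (E_exc <= v_th) stop("neuron_params: E_exc must be above v_th")
  if (theta_plus < 0 || t_refrac < 0)
    stop("neuron_params: theta_plus and t_refrac must be >= 0")
  structure(p, class = "neuron_params")
}

#' Inhibitory-population defaults
#'
#' The inhibitory relay neurons of the winner-take-all circuit use a
#' faster membrane and a lower threshold than the plastic excitatory
#' population, so that a single excitatory spike reliably triggers its
#' one-to-one inhibitory partner.  No threshold adaptation is applied.
#'
#' @param ... Overrides passed to [neuron_params()].
#' @return A `neuron_params` object.
#' @export
inhibitory_params <- function(...) {
  defaults <- list(tau_m = 10, v_r = -60, v_th = -40, theta_plus = 0)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(neuron_params, defaults)
}

#' Triplet STDP parameters
#'
#' The triplet rule keeps one presynaptic trace `x` and two postsynaptic
#' traces `y1` (fast) and `y2` (slow), each decaying exponentially and
#' reset to 1 at its owner's spike.  A presynaptic spike at synapse
#' (j, i) depresses the weight by `mu_pre * y1_i`; a postsynaptic spike
#' potentiates it by `mu_post * x_j * y2_i` (with `y2_i` taken before its
#' own reset).  Weights are clipped to `[w_min, w_max]`.
#'
#' @param tau_x Presynaptic trace time constant (ms).
#' @param tau_y1,tau_y2 Fast and slow postsynaptic trace time constants
#'   (ms).
#' @param mu_pre Depression rate.
#' @param mu_post Potentiation rate.
#' After each training image the active input weights of every excitatory
#' neuron are divisively renormalized to the total `norm_frac * n_input *
#' w_max`, the homeostatic mechanism that keeps neurons competing for
#' distinct input features; frozen and removed synapses are excluded and
#' never rescaled.  Set `norm_frac = 0` to disable.
#'
#' @param w_max Maximum weight (dimensionless conductance units).
#' @param w_min Minimum weight; fixed at 0.
#' @param norm_frac Target total active input weight per neuron, as a
#'   fraction of `n_input * w_max`; 0 disables normalization.
#' @return A list of class `plasticity_params`.
#' @export
plasticity_params <- function(tau_x = 8, tau_y1 = 16, tau_y2 = 32,
                              mu_pre = 1e-4, mu_post = 0.01,
                              w_max = 1, w_min = 0, norm_frac = 0.1) {
  p <- list(tau_x = tau_x, tau_y1 = tau_y1, tau_y2 = tau_y2,
            mu_pre = mu_pre, mu_post = mu_post,
            w_max = w_max, w_min = w_min, norm_frac = norm_frac)
  stopifnot(vapply(p, is.numeric, TRUE), vapply(p, length, 1L) == 1L)
  if (!all(is.finite(unlist(p)))) stop("plasticity_params: non-finite value")
  if (tau_x <= 0 || tau_y1 <= 0 || tau_y2 <= 0)
    stop("plasticity_params: trace time constants must be > 0")
  if (mu_pre < 0 || mu_post < 0)
    stop("plasticity_params: learning rates must be >= 0")
  if (w_min != 0) stop("plasticity_params: w_min is fixed at 0")
  if (w_max <= w_min) stop("plasticity_params: w_max must be > w_min")
  if (norm_frac < 0 || norm_frac > 1)
    stop("plasticity_params: norm_frac must be in [0, 1]")
  structure(p, class = "plasticity_params")
}

#' Network architecture configuration
#'
#' Describes the two-layer winner-take-all architecture: `grid_h * grid_w`
#' Poisson input units fully connected to `n_exc` excitatory neurons, each
#' excitatory neuron driving one inhibitory partner (weight `w_exc_inh`),
#' and each inhibitory neuron inhibiting every excitatory neuron except
#' its source (weight `w_inh_exc`).
#'
#' @param grid_h,grid_w Input image dimensions.
#' @param n_exc Number of excitatory neurons (the inhibitory count
#'   equals it).
#' @param w_exc_inh Fixed one-to-one excitatory-to-inhibitory weight
#'   (conductance units).
#' @param w_inh_exc Fixed all-but-self inhibitory-to-excitatory weight.
#' @param present_ms Image presentation duration (ms).
#' @param rest_ms Silent period between images (ms).
#' @param max_rate_hz Poisson rate for a pixel at intensity 255.
#' @param dt Integration step (ms); must not exceed the smallest
#'   conductance time constant.
#' @return A list of class `arch_config` with derived fields `n_input`
#'   and `n_inh`.
#' @export
arch_config <- function(grid_h = 28, grid_w = 28, n_exc = 100,
                        w_exc_inh = 10.4, w_inh_exc = 17.0,
                        present_ms = 350, rest_ms = 150,
                        max_rate_hz = 63.75, dt = 0.5) {
  if (grid_h < 1 || grid_w < 1 || n_exc < 1)
    stop("arch_config: dimensions must be positive")
  if (w_exc_inh < 0 || w_inh_exc < 0)
    stop("arch_config: fixed WTA weights must be >= 0")
  if (present_ms <= 0 || rest_ms < 0)
    stop("arch_config: present_ms must be > 0 and rest_ms >= 0")
  if (max_rate_hz < 0) stop("arch_config: max_rate_hz must be >= 0")
  if (dt <= 0) stop("arch_config: dt must be > 0")
  structure(list(grid_h = as.integer(grid_h), grid_w = as.integer(grid_w),
                 n_input = as.integer(grid_h * grid_w),
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_exc),
                 w_exc_inh = w_exc_inh, w_inh_exc = w_inh_exc,
                 present_ms = present_ms, rest_ms = rest_ms,
                 max_rate_hz = max_rate_hz, dt = dt),
            class = "arch_config")
}

#' Create a bank of plastic synapses
#'
#' A synapse bank holds the plastic input-to-excitatory weight matrix and
#' a per-synapse status flag: `active` synapses transmit and learn,
#' `frozen` synapses transmit at a fixed weight but never learn (soft
#' pruning), and `removed` synapses neither transmit nor learn.
#'
#' @param w Numeric weight matrix, inputs in rows, excitatory neurons in
#'   columns; all entries in `[0, w_max]`.
#' @param status Integer matrix of the same shape (0 = active,
#'   1 = frozen, 2 = removed), or a single status for all synapses.
#' @param w_max Weight upper bound used for validation.
#' @return A list of class `synapse_bank` with elements `w` and `status`.
#' @export
#' @examples
#' b <- synapse_bank(matrix(0.1, 4, 2))
#' connectivity(b)
synapse_bank <- function(w, status = 0L, w_max = 1) {
  w <- as.matrix(w)
  if (!is.numeric(w) || anyNA(w)) stop("synapse_bank: w must be numeric")
  if (any(w < 0 | w > w_max)) stop("synapse_bank: weights outside [0, w_max]")
  if (length(status) == 1L) {
    status <- matrix(as.integer(status), nrow(w), ncol(w))
  } else {
    status <- matrix(as.integer(status), nrow(w), ncol(w))
  }
  if (!all(status %in% 0:2)) stop("synapse_bank: invalid status codes")
  structure(list(w = w, status = status), class = "synapse_bank")
}

#' Initial neuron state at rest
#'
#' @param n Number of neurons.
#' @param params A [neuron_params()] object supplying the resting
#'   potential.
#' @return A list of class `neuron_state` with vectors `v`, `g_e`, `g_i`,
#'   `theta`, `refrac_left`.
#' @export
neuron_state <- function(n, params = neuron_params()) {
  structure(list(v = rep(params$v_r, n), g_e = numeric(n), g_i = numeric(n),
                 theta = numeric(n), refrac_left = numeric(n)),
            class = "neuron_state")
}

#' Initial STDP trace state
#'
#' @param n_pre Number of presynaptic (input) units.
#' @param n_post Number of postsynaptic (excitatory) neurons.
#' @return A list of class `trace_state` with vectors `x`, `y1`, `y2`,
#'   all zero.
#' @export
trace_state <- function(n_pre, n_post) {
  structure(list(x = numeric(n_pre), y1 = numeric(n_post),
                 y2 = numeric(n_post)),
            class = "trace_state")
}
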