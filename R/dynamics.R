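#' Advance LIF neurons one time step
#'
#' Conductances are decayed by their exact exponential factors and then
#' incremented by the summed weight of arriving spikes; the membrane
#' potential is advanced by one explicit-Euler step; a neuron spikes when
#' it is not refractory and `v >= v_th + theta`.  On a spike the membrane
#' is reset to `v_r`, the adaptive threshold is incremented by
#' `theta_plus`, and the refractory timer is set.  The adaptive threshold
#' decays exponentially with `tau_theta` every step.
#'
#' @param state A [neuron_state()] object.
#' @param params A [neuron_params()] object.
#' @param exc_input Per-neuron summed weight of arriving excitatory
#'   spikes (added to `g_e` after decay).
#' @param inh_input Same for inhibitory spikes (added to `g_i`).
#' @param dt Time step (ms); must satisfy `0 < dt <= tau_ge`.
#' @return A list with elements `state` (updated) and `fired` (logical
#'   per neuron).
#' @export
#' @examples
#' st <- neuron_state(3)
#' out <- step_neurons(st, neuron_params(), exc_input = c(0, 0.5, 0), dt = 0.5)
#' out$fired
step_neurons <- function(state, params, exc_input = 0, inh_input = 0,
                         dt = 0.5) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("step_neurons: dt must be a positive scalar")
  if (dt > params$tau_ge)
    stop("step_neurons: dt must not exceed tau_ge for stability")
  n <- length(state$v)
  exc_input <- rep_len(exc_input, n)
  inh_input <- rep_len(inh_input, n)
  if (any(exc_input < 0) || any(inh_input < 0))
    stop("step_neurons: inputs must be non-negative")
  if (!all(is.finite(c(state$v, state$g_e, state$g_i, state$theta))))
    stop("step_neurons: non-finite state values")

  g_e <- state$g_e * exp(-dt / params$tau_ge) + exc_input
  g_i <- state$g_i * exp(-dt / params$tau_gi) + inh_input
  refrac <- state$refrac_left
  active <- refrac <= 0
  v <- state$v
  dv <- ((params$v_r - v) - g_e * (v - params$E_exc) -
           g_i * (v - params$E_inh)) * dt / params$tau_m
  v <- ifelse(active, v + dv, v)
  refrac <- ifelse(active, refrac, refrac - dt)
  theta <- state$theta * exp(-dt / params$tau_theta)
  fired <- active & v >= params$v_th + theta
  v[fired] <- params$v_r
  theta[fired] <- theta[fired] + params$theta_plus
  refrac[fired] <- params$t_refrac
  state$v <- v
  state$g_e <- g_e
  state$g_i <- g_i
  state$theta <- theta
  state$refrac_left <- refrac
  list(state = state, fired = fired)
}

#' Decay STDP traces
#'
#' Multiplies each trace by its exact exponential decay factor
#' `exp(-dt / tau)`.  Resets to 1 at the owner's spike are applied by
#' [stdp_on_pre()] and [stdp_on_post()], not here.
#'
#' @param traces A [trace_state()] object.
#' @param dt Time step (ms), positive.
#' @param params A [plasticity_params()] object.
#' @return The decayed `trace_state`.
#' @export
decay_traces <- function(traces, dt, params) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("decay_traces: dt must be a positive scalar")
  if (!all(is.finite(c(traces$x, traces$y1, traces$y2))))
    stop("decay_traces: non-finite trace values")
  traces$x <- traces$x * exp(-dt / params$tau_x)
  traces$y1 <- traces$y1 * exp(-dt / params$tau_y1)
  traces$y2 <- traces$y2 * exp(-dt / params$tau_y2)
  traces
}

#' Apply the presynaptic-spike STDP update
#'
#' When input unit `j` fires, every active synapse (j, i) is depressed by
#' `mu_pre * y1_i` (clipped at 0); removed and frozen synapses are
#' untouched.  The presynaptic trace `x_j` is then reset to 1.
#'
#' @param bank A [synapse_bank()].
#' @param traces A [trace_state()].
#' @param j Presynaptic (input) index.
#' @param params A [plasticity_params()].
#' @return A list with the updated `bank` and `traces`.
#' @export
stdp_on_pre <- function(bank, traces, j, params) {
  if (j < 1 || j > nrow(bank$w)) stop("stdp_on_pre: invalid index j")
  act <- bank$status[j, ] == 0L
  w <- bank$w[j, ]
  w[act] <- pmax(params$w_min, w[act] - params$mu_pre * traces$y1[act])
  bank$w[j, ] <- w
  traces$x[j] <- 1
  list(bank = bank, traces = traces)
}

#' Apply the postsynaptic-spike STDP update
#'
#' When excitatory neuron `i` fires, every active synapse (j, i) is
#' potentiated by `mu_post * x_j * y2_i`, using the value of `y2_i`
#' immediately before its own reset, and clipped at `w_max`.  Both
#' postsynaptic traces `y1_i` and `y2_i` are then reset to 1.
#'
#' @inheritParams stdp_on_pre
#' @param i Postsynaptic (excitatory) index.
#' @return A list with the updated `bank` and `traces`.
#' @export
stdp_on_post <- function(bank, traces, i, params) {
  if (i < 1 || i > ncol(bank$w)) stop("stdp_on_post: invalid index i")
  act <- bank$status[, i] == 0L
  w <- bank$w[, i]
  w[act] <- pmin(params$w_max, w[act] + params$mu_post * traces$x[act] *
                   traces$y2[i])
  bank$w[, i] <- w
  traces$y1[i] <- 1
  traces$y2[i] <- 1
  list(bank = bank, traces = traces)
}
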