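#' Pruning-threshold schedule over time
#'
#' The global pruning threshold starts at `wth0` when pruning begins
#' (after `t_m` training images) and is re-evaluated at every pruning
#' step, i.e. every `batch` images.  Three adaptation families are
#' supported, indexed by the pruning-step index `k`:
#' \itemize{
#'   \item `f1_exponential`: `wth0 * a^k` (slow first, fast later),
#'   \item `f2_saturating`: `w_max - (w_max - wth0) * b^(-k)` (fast
#'     first, saturating),
#'   \item `f3_linear`: `wth0 + c * k`,
#'   \item `constant`: `wth0` at every step.
#' }
#' All evaluated thresholds are confined to `[wth0, w_max]`; a threshold
#' below `w_max` guarantees the schedule can never prune the entire
#' network.  A neutral factor (`a = 1`, `b = 1`, or `c = 0`) makes any
#' family identical to `constant`.
#'
#' @param kind Schedule family (short forms `"f1"`, `"f2"`, `"f3"`
#'   accepted).
#' @param wth0 Initial pruning threshold (weight units).
#' @param factor Adaptation factor `a`, `b`, or `c`; ignored for
#'   `constant`.
#' @param t_m Number of training images before pruning starts.
#' @param batch Images per pruning step.
#' @param w_max Maximum weight (cap).
#' @return A list of class `time_schedule`.
#' @export
#' @examples
#' sch <- time_schedule("f1", wth0 = 0.036, factor = 1.3)
#' eval_time_threshold(sch, k = 2)
time_schedule <- function(kind = c("f1_exponential", "f2_saturating",
                                   "f3_linear", "constant",
                                   "f1", "f2", "f3"),
                          wth0 = 0.036, factor = 1,
                          t_m = 30000, batch = 5000, w_max = 1) {
  kind <- match.arg(kind)
  kind <- switch(kind, f1 = "f1_exponential", f2 = "f2_saturating",
                 f3 = "f3_linear", kind)
  if (factor < 0) stop("time_schedule: adaptation factor must be >= 0")
  if (wth0 < 0 || wth0 >= w_max)
    stop("time_schedule: wth0 must lie in [0, w_max)")
  if (t_m < 0 || batch < 1) stop("time_schedule: invalid t_m or batch")
  neutral <- switch(kind,
                    f1_exponential = factor == 1,
                    f2_saturating = factor == 1,
                    f3_linear = factor == 0,
                    constant = TRUE)
  structure(list(kind = kind, wth0 = wth0, factor = factor,
                 t_m = as.integer(t_m), batch = as.integer(batch),
                 w_max = w_max, neutral = neutral),
            class = "time_schedule")
}

#' Evaluate a time schedule at a pruning step
#'
#' @param schedule A [time_schedule()].
#' @param k Pruning-step index (0 at the first pruning step, at `t_m`
#'   images).
#' @return The threshold value, clamped to `[wth0, w_max]`.
#' @export
eval_time_threshold <- function(schedule, k) {
  if (any(k < 0)) stop("eval_time_threshold: k must be >= 0")
  # a neutral factor is exactly the constant schedule (no FP round-trip)
  if (schedule$neutral) return(rep(schedule$wth0, length(k)))
  v <- switch(schedule$kind,
              f1_exponential = schedule$wth0 * schedule$factor^k,
              f2_saturating = schedule$w_max -
                (schedule$w_max - schedule$wth0) * schedule$factor^(-k),
              f3_linear = schedule$wth0 + schedule$factor * k,
              constant = rep(schedule$wth0, length(k)))
  pmin(schedule$w_max, pmax(schedule$wth0, v))
}

#' Average per-neuron spike counts over a batch
#'
#' @param spike_log Matrix of per-image, per-excitatory-neuron spike
#'   counts (images in rows) for one batch.
#' @return Mean spikes per image for each neuron.
#' @export
compute_batch_spike_counts <- function(spike_log) {
  spike_log <- as.matrix(spike_log)
  if (nrow(spike_log) == 0) stop("compute_batch_spike_counts: empty batch")
  colMeans(spike_log)
}

#' Group neurons by firing activity
#'
#' Neurons are partitioned into groups of similar batch-average spike
#' count: starting from the minimum count `S` of the ungrouped neurons,
#' every ungrouped neuron with count in `[S, S + SI]` (inclusive at both
#' ends) joins the group; this repeats until all neurons are grouped.
#' Groups are ordered by ascending minimum count, so the within-group
#' spread never exceeds `SI`, and `SI = Inf` yields a single group.
#'
#' @param counts Per-neuron average spike counts.
#' @param SI Spike-count interval (> 0, possibly `Inf`).
#' @return An object of class `group_partition`: a list of groups, each
#'   with `members` (neuron indices), `S` (minimum count), and `N`
#'   (size); the partition carries `counts` and `SI` as attributes.
#' @export
#' @examples
#' group_neurons(c(0, 10, 40, 100), SI = 30)
group_neurons <- function(counts, SI = 30) {
  if (!is.numeric(SI) || length(SI) != 1L || SI <= 0)
    stop("group_neurons: SI must be > 0 (possibly Inf)")
  if (anyNA(counts)) stop("group_neurons: counts must not contain NA")
  remaining <- seq_along(counts)
  groups <- list()
  while (length(remaining) > 0) {
    S <- min(counts[remaining])
    sel <- counts[remaining] <= S + SI  # counts >= S by construction
    members <- remaining[sel]
    groups[[length(groups) + 1L]] <-
      list(members = members, S = S, N = length(members))
    remaining <- remaining[!sel]
  }
  structure(groups, class = "group_partition", counts = counts, SI = SI)
}

#' Per-group pruning thresholds
#'
#' The current global threshold is assigned to the first group (G0, the
#' weakest firers) and adapted across groups with the chosen function
#' family evaluated at the group index `n`: `f1`: `base * a^n`; `f2`:
#' `w_max - (w_max - base) * b^(-n)`; `f3`: `base + c * n`.  Thresholds
#' are capped at `w_max`.  A neutral factor gives every group exactly the
#' base threshold.
#'
#' @param partition A [group_neurons()] partition.
#' @param base Current global threshold (assigned to G0).
#' @param kind Adaptation family as in [time_schedule()].
#' @param factor Adaptation factor.
#' @param w_max Maximum weight (cap).
#' @return List with `per_group` thresholds and `per_neuron` (broadcast
#'   to every member, in neuron order).
#' @export
assign_group_thresholds <- function(partition, base,
                                    kind = "f1_exponential", factor = 1.15,
                                    w_max = 1) {
  kind <- match.arg(kind, c("f1_exponential", "f2_saturating", "f3_linear",
                            "constant", "f1", "f2", "f3"))
  kind <- switch(kind, f1 = "f1_exponential", f2 = "f2_saturating",
                 f3 = "f3_linear", kind)
  if (factor < 0) stop("assign_group_thresholds: factor must be >= 0")
  n_groups <- length(partition)
  idx <- seq_len(n_groups) - 1
  neutral <- (kind == "constant") ||
    (kind %in% c("f1_exponential", "f2_saturating") && factor == 1) ||
    (kind == "f3_linear" && factor == 0)
  if (neutral) {
    per_group <- rep(base, n_groups)
  } else {
    per_group <- switch(kind,
                        f1_exponential = base * factor^idx,
                        f2_saturating = w_max - (w_max - base) * factor^(-idx),
                        f3_linear = base + factor * idx)
    per_group <- pmin(w_max, per_group)
  }
  counts <- attr(partition, "counts")
  per_neuron <- numeric(length(counts))
  for (g in seq_len(n_groups))
    per_neuron[partition[[g]]$members] <- per_group[g]
  list(per_group = per_group, per_neuron = per_neuron)
}

#' Prune sub-threshold synapses
#'
#' Every active synapse (j, i) with weight strictly below the threshold
#' of its postsynaptic neuron is pruned: removed (the weight is kept but
#' never transmits or learns again) for the hard methods, frozen at its
#' current value (still transmits, never learns) for `soft`.  Removed and
#' frozen synapses are permanent; a second call with the same thresholds
#' prunes nothing new.
#'
#' @param bank A [synapse_bank()] or an `snn_network` (pruned in place).
#' @param thresholds Per-neuron thresholds (recycled if scalar), >= 0.
#' @param method One of `"constant"`, `"APT"`, `"APN"`, `"APTN"`,
#'   `"post_training"` (remove) or `"soft"` (freeze).
#' @return List with the updated `bank` and `n_new`, the number of newly
#'   pruned synapses.  For a network input the network itself is
#'   returned as `bank`.
#' @export
prune_batch <- function(bank, thresholds, method = "constant") {
  method <- match.arg(method, c("constant", "APT", "APN", "APTN",
                                "post_training", "soft"))
  w <- bank$w
  status <- bank$status
  n_exc <- ncol(w)
  thresholds <- rep_len(thresholds, n_exc)
  if (any(thresholds < 0)) stop("prune_batch: thresholds must be >= 0")
  thr <- matrix(thresholds, nrow(w), n_exc, byrow = TRUE)
  mask <- status == 0L & w < thr
  n_new <- sum(mask)
  status[mask] <- if (method == "soft") 1L else 2L
  bank$status <- status
  if (any(colSums(status != 2L) == 0))
    warning("prune_batch: at least one neuron lost all its synapses")
  list(bank = bank, n_new = n_new)
}

#' Fraction of unpruned synapses
#'
#' Connectivity is the fraction of synapses of the plastic projection
#' that have not been removed.  Soft-frozen synapses remain in the
#' network, so soft pruning keeps connectivity at 1.
#'
#' @param x A `synapse_bank`, `snn_network`, or `snn_wta` fit.
#' @return Fraction in `[0, 1]`.
#' @export
connectivity <- function(x) {
  status <- extract_status(x)
  mean(status != 2L)
}

#' Fraction of never-pruned synapses
#'
#' Counts only active synapses, so soft-frozen synapses are excluded;
#' this is the "unpruned percentage" axis used when comparing against
#' soft pruning.
#'
#' @inheritParams connectivity
#' @return Fraction in `[0, 1]`.
#' @export
unpruned_fraction <- function(x) {
  status <- extract_status(x)
  mean(status == 0L)
}

extract_status <- function(x) {
  if (inherits(x, "snn_wta")) return(x$network$status)
  if (inherits(x, "snn_network")) return(x$status)
  if (inherits(x, "synapse_bank")) return(x$status)
  stop("expected a synapse_bank, snn_network, or snn_wta object")
}

#' Pruning method configuration
#'
#' Bundles the choices of the online pruning controller: the method, the
#' time schedule of the global threshold, the neuron-adaptation function
#' applied across firing-activity groups, and the grouping interval.
#' Defaults follow the selections reported for the 100-neuron network:
#' time family `f1` with `a = 1.3`, neuron family `f1` with `a = 1.15`,
#' `SI = 30`, pruning start after 30,000 images, batch 5,000.  For the
#' 800-neuron network the reported time factor is 1.2.
#'
#' @param method One of `"none"`, `"constant"`, `"APT"`, `"APN"`,
#'   `"APTN"`, `"soft"`, `"post_training"`.
#' @param wth0 Initial (or constant) pruning threshold.
#' @param time_kind,time_factor Time-adaptation family and factor (used
#'   by APT and APTN).
#' @param neuron_kind,neuron_factor Neuron-adaptation family and factor
#'   (used by APN and APTN).
#' @param SI Spike-count interval for grouping (APN/APTN); `Inf` gives a
#'   single group.
#' @param t_m Training images before pruning starts.
#' @param batch Images per pruning step.
#' @param w_max Maximum weight (threshold cap).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(method = c("none", "constant", "APT", "APN",
                                    "APTN", "soft", "post_training"),
                         wth0 = 0.036,
                         time_kind = "f1_exponential", time_factor = 1.3,
                         neuron_kind = "f1_exponential",
                         neuron_factor = 1.15,
                         SI = 30, t_m = 30000, batch = 5000, w_max = 1) {
  method <- match.arg(method)
  # methods without time adaptation keep the global threshold at wth0
  tf <- if (method %in% c("APT", "APTN")) time_factor else
    switch(substr(time_kind, 1, 2), f3 = 0, 1)
  schedule <- time_schedule(time_kind, wth0 = wth0, factor = tf,
                            t_m = t_m, batch = batch, w_max = w_max)
  nf <- if (method %in% c("APN", "APTN")) neuron_factor else
    switch(substr(neuron_kind, 1, 2), f3 = 0, 1)
  si <- if (method %in% c("APN", "APTN")) SI else Inf
  if (!method %in% c("none")) {
    if (wth0 < 0) stop("prune_config: wth0 must be >= 0")
  }
  structure(list(method = method, wth0 = wth0,
                 schedule = schedule,
                 neuron_kind = schedule_kind_name(neuron_kind),
                 neuron_factor = nf, SI = si,
                 t_m = as.integer(t_m), batch = as.integer(batch),
                 w_max = w_max),
            class = "prune_config")
}

schedule_kind_name <- function(kind) {
  kind <- match.arg(kind, c("f1_exponential", "f2_saturating", "f3_linear",
                            "constant", "f1", "f2", "f3"))
  switch(kind, f1 = "f1_exponential", f2 = "f2_saturating",
         f3 = "f3_linear", kind)
}

#' Internal state of the online pruning controller
#' @param config A [prune_config()].
#' @return A `prune_state` environment with the step index and current
#'   global threshold.
#' @keywords internal
new_prune_state <- function(config) {
  st <- new.env(parent = emptyenv())
  st$k <- 0L
  st$current_global <- eval_time_threshold(config$schedule, 0L)
  st$log <- list()
  class(st) <- "prune_state"
  st
}

#' One step of the online adaptive pruning controller
#'
#' Implements a single batch-boundary pruning action: batch-average spike
#' counts are grouped (APN/APTN; APT and constant use one group), the
#' current global threshold is assigned to G0 and adapted across groups
#' with the neuron function, sub-threshold active synapses are pruned,
#' and finally the global threshold is advanced with the time schedule
#' (APT/APTN; frozen otherwise).
#'
#' @param net An `snn_network` (pruned in place).
#' @param config A [prune_config()] with an online method.
#' @param state A [new_prune_state()] environment.
#' @param batch_counts Per-image, per-neuron spike counts for the batch
#'   just finished.
#' @return Invisibly, the log row (list) for this step.
#' @export
aptn_step <- function(net, config, state, batch_counts) {
  counts <- compute_batch_spike_counts(batch_counts)
  base <- state$current_global
  if (config$method %in% c("APN", "APTN")) {
    part <- group_neurons(counts, config$SI)
  } else {
    part <- group_neurons(counts, Inf)
  }
  thr <- assign_group_thresholds(part, base, config$neuron_kind,
                                 config$neuron_factor, config$w_max)
  res <- prune_batch(net, thr$per_neuron, config$method)
  row <- list(k = state$k, global_threshold = base,
              n_groups = length(part),
              thresholds = paste(signif(thr$per_group, 6), collapse = ";"),
              newly_pruned = res$n_new,
              connectivity = connectivity(net))
  state$log[[length(state$log) + 1L]] <- row
  if (config$method %in% c("APT", "APTN")) {
    state$k <- state$k + 1L
    state$current_global <- eval_time_threshold(config$schedule, state$k)
  } else {
    state$k <- state$k + 1L
  }
  invisible(row)
}

#' Prune a trained network once, after training
#'
#' Applies a single uniform-threshold hard prune to a trained model, the
#' post-training baseline: training SOPs are identical to the unpruned
#' run because no synapse is removed while learning.
#'
#' @param fit An `snn_wta` fit (its network is pruned in place).
#' @param wth Uniform pruning threshold.
#' @return The fit, with the prune recorded in `fit$prune_log`.
#' @export
post_training_prune <- function(fit, wth) {
  res <- prune_batch(fit$network, wth, "post_training")
  row <- data.frame(k = 0L, global_threshold = wth, n_groups = 1L,
                    thresholds = as.character(signif(wth, 6)),
                    newly_pruned = res$n_new,
                    connectivity = connectivity(fit$network))
  fit$prune_log <- rbind(fit$prune_log, row)
  fit
}
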