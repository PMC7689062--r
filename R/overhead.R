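#' Hardware-overhead model constants
#'
#' Constants for estimating the cost of running the pruning unit on a
#' synchronous digital neuromorphic system: per-batch clock-cycle and
#' operation counts for the grouping and threshold-adapting phases
#' (assuming at most `n_groups` groups and no parallelism), fixed-point
#' width, per-SOP and per-memory-access energies, and equivalent NAND
#' gate / block-RAM counts for the pruning unit and for a 100-neuron SNN
#' core.
#'
#' @param n_groups Group-count assumption for the grouping/adapting
#'   estimates.
#' @param int_bits,frac_bits Fixed-point integer and fractional widths.
#' @param grouping_cycles,grouping_ops Per-batch cost of the grouping
#'   phase.
#' @param adapting_cycles,adapting_ops Per-batch cost of the
#'   threshold-adapting phase.
#' @param energy_per_sop_pJ Minimum energy per synaptic operation (pJ).
#' @param energy_per_access_pJ Energy per SRAM access (pJ); every pruning
#'   operation is costed as a memory access (worst case).
#' @param gates_prune,brams_prune Equivalent NAND gates and 18 Kb BRAMs
#'   of the pruning unit.
#' @param gates_snn,brams_snn Same for the SNN core.
#' @return A list of class `overhead_model`.
#' @export
overhead_model <- function(n_groups = 20, int_bits = 16, frac_bits = 8,
                           grouping_cycles = 120, grouping_ops = 400,
                           adapting_cycles = 2000, adapting_ops = 1100,
                           energy_per_sop_pJ = 23.6,
                           energy_per_access_pJ = 0.5,
                           gates_prune = 8284, brams_prune = 2,
                           gates_snn = 3.0e6, brams_snn = 50) {
  m <- list(n_groups = n_groups, int_bits = int_bits, frac_bits = frac_bits,
            grouping_cycles = grouping_cycles, grouping_ops = grouping_ops,
            adapting_cycles = adapting_cycles, adapting_ops = adapting_ops,
            energy_per_sop_pJ = energy_per_sop_pJ,
            energy_per_access_pJ = energy_per_access_pJ,
            gates_prune = gates_prune, brams_prune = brams_prune,
            gates_snn = gates_snn, brams_snn = brams_snn)
  if (!all(unlist(m) > 0)) stop("overhead_model: all constants must be > 0")
  structure(m, class = "overhead_model")
}

#' Per-batch cycle and operation estimates for the pruning unit
#'
#' The weight-pruning phase touches every synapse once through a single
#' memory port: `n_input * n_exc` cycles and `2 * n_input * n_exc`
#' operations (one access plus one comparison per synapse).  Grouping and
#' adapting use the model's per-batch constants.  Per-image averages are
#' the per-batch sums divided by the batch size.
#'
#' @param n_input,n_exc Plastic projection dimensions.
#' @param model An [overhead_model()].
#' @param batch_size Images per pruning batch (for the per-image
#'   averages).
#' @return List with `per_batch` (data frame of phase, cycles, ops),
#'   `total_cycles`, `total_ops`, `cycles_per_image`, `ops_per_image`.
#' @export
#' @examples
#' estimate_pruning_overhead(784, 100)$per_batch
estimate_pruning_overhead <- function(n_input, n_exc,
                                      model = overhead_model(),
                                      batch_size = 5000) {
  if (n_input < 1 || n_exc < 1 || batch_size < 1)
    stop("estimate_pruning_overhead: sizes must be positive")
  wp_cycles <- n_input * n_exc
  wp_ops <- 2 * n_input * n_exc
  per_batch <- data.frame(
    phase = c("grouping", "adapting", "weight_pruning"),
    cycles = c(model$grouping_cycles, model$adapting_cycles, wp_cycles),
    ops = c(model$grouping_ops, model$adapting_ops, wp_ops))
  list(per_batch = per_batch,
       total_cycles = sum(per_batch$cycles),
       total_ops = sum(per_batch$ops),
       cycles_per_image = sum(per_batch$cycles) / batch_size,
       ops_per_image = sum(per_batch$ops) / batch_size)
}

#' Energy of synaptic operations and pruning operations per image
#'
#' @param sops_per_image Synaptic operations per image.
#' @param pruning_ops_per_image Pruning-unit operations per image.
#' @param model An [overhead_model()].
#' @return List with `sop_energy_pJ`, `sop_energy_uJ`,
#'   `pruning_energy_pJ`, and `ratio` (pruning / SOP energy).
#' @export
#' @examples
#' estimate_energy(96099, 18)$sop_energy_uJ  # about 2.3 uJ
estimate_energy <- function(sops_per_image, pruning_ops_per_image,
                            model = overhead_model()) {
  if (sops_per_image < 0 || pruning_ops_per_image < 0)
    stop("estimate_energy: counts must be >= 0")
  sop_pJ <- sops_per_image * model$energy_per_sop_pJ
  prune_pJ <- pruning_ops_per_image * model$energy_per_access_pJ
  list(sop_energy_pJ = sop_pJ,
       sop_energy_uJ = sop_pJ * 1e-6,
       pruning_energy_pJ = prune_pJ,
       ratio = if (sop_pJ > 0) prune_pJ / sop_pJ else NA_real_)
}

#' Area overhead of the pruning unit
#'
#' @param model An [overhead_model()].
#' @return Ratio of pruning-unit NAND gates to SNN NAND gates.
#' @export
#' @examples
#' 100 * gate_ratio()  # about 0.3 (percent)
gate_ratio <- function(model = overhead_model()) {
  model$gates_prune / model$gates_snn
}
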