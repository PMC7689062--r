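#' Synaptic operations per image
#'
#' Training SOPs comprise weight accumulations plus STDP updates of the
#' plastic projection; inference (and assignment) SOPs comprise weight
#' accumulations only.  Fixed lateral events are excluded: pruning cannot
#' affect them, and the reported reductions should reflect the method.
#'
#' @param ledger A ledger (or fit/network; see [ledger_summary()]).
#' @param phase `"train"`, `"assign"`, or `"infer"`.
#' @return SOPs per image for that phase (NA if no images were run).
#' @export
sops_per_image <- function(ledger, phase = c("train", "infer", "assign")) {
  phase <- match.arg(phase)
  l <- ledger_summary(ledger)
  n <- l[[paste0("images_", phase)]]
  if (n == 0) return(NA_real_)
  total <- l[[paste0(phase, "_accum")]]
  if (phase == "train")
    total <- total + l$train_stdp_pre + l$train_stdp_post
  total / n
}

#' Percent SOP reduction of a pruned run against its baseline
#'
#' The reduction is the reduced percentage of SOPs/image by pruning
#' against the SOPs/image of the same network without pruning.
#'
#' @param pruned,baseline Ledgers (or fits) of the pruned and unpruned
#'   runs.
#' @return List with `train_pct` and `infer_pct`.
#' @export
normalized_reduction <- function(pruned, baseline) {
  list(train_pct = 100 * (1 - sops_per_image(pruned, "train") /
                            sops_per_image(baseline, "train")),
       infer_pct = 100 * (1 - sops_per_image(pruned, "infer") /
                            sops_per_image(baseline, "infer")))
}

#' Figure of merit for a pruned network
#'
#' `FOM = accuracy loss (percentage points) x normalized total SOPs per
#' image`, where the normalized total is `(train + infer SOPs/image)`
#' divided by the unpruned run's total.  Lower is better; the FOM trades
#' accuracy degradation against remaining computational cost.
#'
#' @param accuracy_loss Accuracy loss in percentage points against the
#'   same-seed unpruned baseline.
#' @param norm_total Normalized total SOPs/image, in `[0, 1]` for pruned
#'   runs.
#' @return The figure of merit.
#' @export
compute_fom <- function(accuracy_loss, norm_total) {
  if (any(norm_total < 0)) stop("compute_fom: norm_total must be >= 0")
  accuracy_loss * norm_total
}

#' Build a figure-of-merit report for a pruned run
#'
#' @param pruned,baseline Fits (or ledgers) of the pruned and unpruned
#'   runs.
#' @param accuracy_pruned,accuracy_baseline Test accuracies (fractions).
#' @return A one-row data frame of class `fom_report`: connectivity,
#'   accuracies, accuracy loss (percentage points), per-phase SOPs/image,
#'   normalized train/infer/total, and the FOM.
#' @export
fom_report <- function(pruned, baseline, accuracy_pruned,
                       accuracy_baseline) {
  tr_p <- sops_per_image(pruned, "train")
  tr_b <- sops_per_image(baseline, "train")
  in_p <- sops_per_image(pruned, "infer")
  in_b <- sops_per_image(baseline, "infer")
  loss <- 100 * (accuracy_baseline - accuracy_pruned)
  norm_total <- (tr_p + in_p) / (tr_b + in_b)
  conn <- tryCatch(connectivity(pruned), error = function(e) NA_real_)
  structure(data.frame(connectivity = conn,
                       accuracy = accuracy_pruned,
                       accuracy_baseline = accuracy_baseline,
                       accuracy_loss = loss,
                       train_sops_image = tr_p,
                       infer_sops_image = in_p,
                       norm_train = tr_p / tr_b,
                       norm_infer = in_p / in_b,
                       norm_total = norm_total,
                       fom = compute_fom(loss, norm_total)),
            class = c("fom_report", "data.frame"))
}

#' Pick the connectivity with the best figure of merit
#'
#' @param sweep A data frame with columns `connectivity` and `fom` (e.g.
#'   rows of [fom_report()]).
#' @return The connectivity value at the minimum FOM.
#' @export
select_best_connectivity <- function(sweep) {
  if (nrow(sweep) == 0) stop("select_best_connectivity: empty sweep")
  sweep$connectivity[which.min(sweep$fom)]
}
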