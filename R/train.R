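coerce_images <- function(images) {
  if (inherits(images, "image_dataset")) {
    return(list(x = as_image_matrix(images), grid = dim(images$images)[2:3],
                labels = images$labels))
  }
  if (is.array(images) && length(dim(images)) == 3) {
    d <- dim(images)
    return(list(x = matrix(images, d[1], d[2] * d[3]), grid = d[2:3],
                labels = NULL))
  }
  if (is.matrix(images)) return(list(x = images, grid = NULL, labels = NULL))
  stop("images must be an image_dataset, an n x h x w array, or a matrix")
}

#' Train an unsupervised WTA spiking network, optionally pruning online
#'
#' Runs the full training loop: every image is Poisson rate-coded and
#' presented for `present_ms` followed by `rest_ms` of silence while
#' triplet STDP and threshold adaptation operate; when an online pruning
#' method is configured, the adaptive pruning controller fires at every
#' batch boundary once `t_m` images have been seen, and the
#' `post_training` method prunes once after the pass.  If labels are
#' available, a label-assignment pass with plasticity frozen follows.
#'
#' @param images Training images: an `image_dataset`, an `n x h x w`
#'   array, or an `n x n_input` matrix of intensities in `[0, 255]`.
#' @param labels Class labels (taken from the dataset if omitted); `NULL`
#'   trains without label assignment.
#' @param arch An [arch_config()]; the grid defaults to the image
#'   dimensions and `n_exc = 100`.
#' @param neuron,neuron_inh,plasticity Model parameters.
#' @param prune A [prune_config()]; `method = "none"` trains unpruned.
#' @param seed Seed for weight initialization, rate coding, and the
#'   assignment pass.
#' @param epochs Passes over the image stream (default one).
#' @param monitor_window Images per dynamics-monitoring window.
#' @param assign Whether to run the label-assignment pass.
#' @param n_assign Size of the assignment subset (default: the full
#'   training set).
#' @param verbose Print progress.
#' @return An object of class `snn_wta` with the live `network`
#'   environment, the label `assignment`, per-window `dynamics`, the
#'   per-batch `prune_log`, per-image training `spike_counts`, and the
#'   configuration.
#' @export
#' @examples
#' d <- make_synthetic(synthetic_spec(), n_train = 20, n_test = 5)
#' fit <- train_snn(d$train, arch = arch_config(16, 16, n_exc = 5),
#'                  monitor_window = 10, seed = 1)
#' connectivity(fit)
train_snn <- function(images, labels = NULL,
                      arch = NULL,
                      neuron = neuron_params(),
                      neuron_inh = inhibitory_params(),
                      plasticity = plasticity_params(),
                      prune = prune_config("none"),
                      seed = 1, epochs = 1,
                      monitor_window = 5000,
                      assign = TRUE, n_assign = NULL,
                      verbose = FALSE) {
  cl <- match.call()
  ci <- coerce_images(images)
  x <- ci$x
  if (is.null(labels)) labels <- ci$labels
  if (is.null(arch)) {
    if (is.null(ci$grid))
      stop("train_snn: supply arch when images carry no grid dimensions")
    arch <- arch_config(grid_h = ci$grid[1], grid_w = ci$grid[2])
  }
  if (ncol(x) != arch$n_input)
    stop("train_snn: image size does not match arch$n_input")
  if (!is.null(labels) && length(labels) != nrow(x))
    stop("train_snn: labels and images differ in length")
  if (nrow(x) < 1) stop("train_snn: empty image stream")

  set.seed(seed)
  net <- new_snn_network(arch, neuron, neuron_inh, plasticity)

  stream <- rep(seq_len(nrow(x)), epochs)
  n <- length(stream)
  spike_counts <- matrix(0L, n, arch$n_exc)
  dw_log <- matrix(0, n, 3,
                   dimnames = list(NULL, c("n", "sum", "sumsq")))
  online <- prune$method %in% c("constant", "APT", "APN", "APTN", "soft")
  pstate <- new_prune_state(prune)

  for (m in seq_len(n)) {
    rec <- present_image(net, x[stream[m], ], plastic = TRUE)
    spike_counts[m, ] <- rec$counts
    dw_log[m, ] <- c(rec$dw_n, rec$dw_sum, rec$dw_sumsq)
    if (online && m >= prune$t_m && (m - prune$t_m) %% prune$batch == 0) {
      win <- max(1, m - prune$batch + 1):m
      aptn_step(net, prune, pstate,
                spike_counts[win, , drop = FALSE])
      if (verbose)
        message(sprintf("prune step k=%d at image %d: connectivity %.3f",
                        pstate$k - 1L, m, connectivity(net)))
    }
    if (verbose && m %% monitor_window == 0)
      message(sprintf("image %d / %d", m, n))
  }

  prune_log <- prune_log_frame(pstate)
  fit <- structure(list(network = net, assignment = NULL,
                        dynamics = compute_training_dynamics(
                          dw_log, spike_counts, monitor_window),
                        prune_log = prune_log,
                        spike_counts = spike_counts,
                        classes = if (!is.null(labels)) sort(unique(labels)),
                        prune = prune, seed = seed,
                        monitor_window = monitor_window,
                        no_signal = NULL,
                        call = cl),
                   class = "snn_wta")

  if (prune$method == "post_training")
    fit <- post_training_prune(fit, prune$wth0)

  if (assign && !is.null(labels)) {
    idx <- seq_len(if (is.null(n_assign)) nrow(x)
                   else min(n_assign, nrow(x)))
    fit$assignment <- assign_labels(net, x[idx, , drop = FALSE],
                                    labels[idx])
    fit$classes <- fit$assignment$classes
  }
  fit
}

prune_log_frame <- function(pstate) {
  if (length(pstate$log) == 0)
    return(data.frame(k = integer(), global_threshold = numeric(),
                      n_groups = integer(), thresholds = character(),
                      newly_pruned = integer(), connectivity = numeric()))
  do.call(rbind, lapply(pstate$log, as.data.frame))
}

#' Per-window training dynamics
#'
#' Aggregates the firing-activity and weight-update monitors over
#' contiguous windows of training images: the mean excitatory spike count
#' per image per neuron, and the mean and population variance of all
#' weight changes applied in the window.
#'
#' @param dw_log Per-image weight-change summaries: a matrix or data
#'   frame with columns `n` (number of updates), `sum`, and `sumsq`.
#' @param spike_log Per-image, per-neuron spike-count matrix aligned with
#'   `dw_log`.
#' @param window Images per window.
#' @return Data frame with one row per window: image range, mean spike
#'   count, update count, `mean_dw`, `var_dw`, and `empty` flagging
#'   windows with no updates (whose moments are `NA`).
#' @export
compute_training_dynamics <- function(dw_log, spike_log, window = 5000) {
  dw_log <- as.matrix(dw_log)
  spike_log <- as.matrix(spike_log)
  if (nrow(dw_log) != nrow(spike_log))
    stop("compute_training_dynamics: logs are not aligned")
  n <- nrow(dw_log)
  starts <- seq(1, n, by = window)
  rows <- lapply(starts, function(s) {
    e <- min(n, s + window - 1)
    nn <- sum(dw_log[s:e, 1])
    if (nn > 0) {
      m <- sum(dw_log[s:e, 2]) / nn
      v <- sum(dw_log[s:e, 3]) / nn - m^2
    } else {
      m <- NA_real_
      v <- NA_real_
    }
    data.frame(window = which(starts == s), first_image = s, last_image = e,
               mean_spike_count = mean(spike_log[s:e, ]),
               n_updates = nn, mean_dw = m, var_dw = max(v, 0),
               empty = nn == 0)
  })
  out <- do.call(rbind, rows)
  out$var_dw[out$empty] <- NA_real_
  out
}

#' Assign class labels to excitatory neurons
#'
#' Runs a dedicated pass over a labeled set with plasticity and threshold
#' adaptation frozen, sums each neuron's spikes per class, and labels the
#' neuron with the class for which it fired the most (ties broken toward
#' the lowest class; neurons silent on every class get the first class
#' and are flagged).
#'
#' @param net An `snn_network` or `snn_wta` fit.
#' @param images Assignment images (matrix, array, or dataset).
#' @param labels Class labels for the assignment images.
#' @return A list of class `label_assignment`: `neuron_labels`,
#'   `class_counts` (neurons x classes), `silent`, `classes`, and
#'   `groups` (neuron indices per class).
#' @export
assign_labels <- function(net, images, labels) {
  if (inherits(net, "snn_wta")) net <- net$network
  x <- coerce_images(images)$x
  classes <- sort(unique(labels))
  reset_transient_state(net)
  counts <- matrix(0, net$arch$n_exc, length(classes),
                   dimnames = list(NULL, as.character(classes)))
  for (m in seq_len(nrow(x))) {
    rec <- present_image(net, x[m, ], plastic = FALSE, phase = "assign")
    k <- match(labels[m], classes)
    counts[, k] <- counts[, k] + rec$counts
  }
  assignment_from_counts(counts, classes)
}

#' Label neurons from a class-wise spike-count matrix
#'
#' @param counts Matrix of summed spike counts, neurons in rows, classes
#'   in columns.
#' @param classes Class values corresponding to the columns.
#' @return A `label_assignment` (see [assign_labels()]).
#' @export
assignment_from_counts <- function(counts, classes = seq_len(ncol(counts)) - 1L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(classes))
    stop("assignment_from_counts: classes do not match count columns")
  best <- apply(counts, 1, which.max)  # ties -> lowest class index
  silent <- rowSums(counts) == 0
  best[silent] <- 1L
  neuron_labels <- classes[best]
  groups <- lapply(seq_along(classes),
                   function(k) which(neuron_labels == classes[k]))
  names(groups) <- as.character(classes)
  structure(list(neuron_labels = neuron_labels, class_counts = counts,
                 silent = silent, classes = classes, groups = groups),
            class = "label_assignment")
}

#' Classify one spike record
#'
#' Returns the class whose labeled neuron group has the highest mean
#' spike count for the image.  Empty groups are excluded; ties go to the
#' lowest class; if every group is silent the first class is returned
#' with attribute `no_signal = TRUE`.
#'
#' @param record A `spike_record` or a per-neuron spike-count vector.
#' @param assignment A [assign_labels()] result.
#' @return The predicted class (with attribute `no_signal`).
#' @export
classify <- function(record, assignment) {
  counts <- if (inherits(record, "spike_record")) record$counts else record
  means <- vapply(assignment$groups, function(g)
    if (length(g) == 0) -Inf else mean(counts[g]), numeric(1))
  if (all(means <= 0)) {
    out <- assignment$classes[1]
    attr(out, "no_signal") <- TRUE
    return(out)
  }
  out <- assignment$classes[which.max(means)]
  attr(out, "no_signal") <- FALSE
  out
}

#' Predict classes for new images
#'
#' Runs inference with plasticity and threshold adaptation frozen and
#' classifies each image from the mean spike count of the labeled neuron
#' groups.
#'
#' @param object An `snn_wta` fit with a label assignment.
#' @param newdata Images (dataset, array, or matrix).
#' @param type `"class"` for predicted classes, `"counts"` for the raw
#'   per-neuron spike-count matrix.
#' @param seed Optional seed for the inference rate coding.
#' @param ... Unused.
#' @return Predicted classes (with a `no_signal` attribute vector) or a
#'   count matrix.
#' @export
predict.snn_wta <- function(object, newdata, type = c("class", "counts"),
                            seed = NULL, ...) {
  type <- match.arg(type)
  if (type == "class" && is.null(object$assignment))
    stop("predict: fit has no label assignment; train with labels")
  x <- coerce_images(newdata)$x
  net <- object$network
  if (!is.null(seed)) set.seed(seed)
  reset_transient_state(net)
  counts <- matrix(0L, nrow(x), net$arch$n_exc)
  for (m in seq_len(nrow(x)))
    counts[m, ] <- present_image(net, x[m, ], plastic = FALSE,
                                 phase = "infer")$counts
  if (type == "counts") return(counts)
  preds <- vector(mode(object$assignment$classes), nrow(x))
  nosig <- logical(nrow(x))
  for (m in seq_len(nrow(x))) {
    p <- classify(counts[m, ], object$assignment)
    preds[m] <- p
    nosig[m] <- attr(p, "no_signal")
  }
  attr(preds, "no_signal") <- nosig
  preds
}

#' Classification accuracy on a labeled test set
#'
#' @param fit An `snn_wta` fit with a label assignment.
#' @param images,labels Test images and labels (labels taken from an
#'   `image_dataset` if omitted).
#' @param seed Optional seed for the inference rate coding.
#' @return Fraction of correctly classified images.
#' @export
evaluate_accuracy <- function(fit, images, labels = NULL, seed = NULL) {
  ci <- coerce_images(images)
  if (is.null(labels)) labels <- ci$labels
  if (is.null(labels)) stop("evaluate_accuracy: labels required")
  preds <- predict(fit, ci$x, seed = seed)
  mean(preds == labels)
}

#' @export
print.snn_wta <- function(x, ...) {
  arch <- x$network$arch
  cat("Unsupervised WTA spiking network\n")
  cat(sprintf("  input %d x %d (%d units) -> %d excitatory / %d inhibitory\n",
              arch$grid_h, arch$grid_w, arch$n_input, arch$n_exc, arch$n_inh))
  cat(sprintf("  trained on %d image presentations (seed %s)\n",
              nrow(x$spike_counts), format(x$seed)))
  cat(sprintf("  pruning: %s; connectivity %.1f%%\n", x$prune$method,
              100 * connectivity(x)))
  if (!is.null(x$assignment))
    cat("  labels assigned over", length(x$assignment$classes), "classes\n")
  invisible(x)
}

#' @export
summary.snn_wta <- function(object, ...) {
  l <- ledger_summary(object)
  out <- list(connectivity = connectivity(object),
              unpruned_fraction = unpruned_fraction(object),
              train_sops_image = sops_per_image(object, "train"),
              infer_sops_image = sops_per_image(object, "infer"),
              neuron_labels = if (!is.null(object$assignment))
                table(object$assignment$neuron_labels),
              silent_neurons = if (!is.null(object$assignment))
                sum(object$assignment$silent),
              prune_steps = nrow(object$prune_log),
              images_train = l$images_train)
  class(out) <- "summary.snn_wta"
  out
}

#' @export
print.summary.snn_wta <- function(x, ...) {
  cat(sprintf("connectivity: %.3f (active fraction %.3f)\n",
              x$connectivity, x$unpruned_fraction))
  cat(sprintf("training SOPs/image: %.1f; inference SOPs/image: %s\n",
              x$train_sops_image,
              ifelse(is.na(x$infer_sops_image), "not measured",
                     sprintf("%.1f", x$infer_sops_image))))
  cat(sprintf("pruning steps: %d; training images: %d\n",
              x$prune_steps, x$images_train))
  if (!is.null(x$neuron_labels)) {
    cat("neurons per class label:\n")
    print(x$neuron_labels)
    cat(sprintf("silent neurons flagged: %d\n", x$silent_neurons))
  }
  invisible(x)
}

#' @export
coef.snn_wta <- function(object, ...) {
  object$network$w
}

#' Plot receptive fields or training dynamics
#'
#' @param x An `snn_wta` fit.
#' @param which `"weights"` draws each neuron's weight vector as an image
#'   (removed synapses at zero); `"dynamics"` plots the per-window firing
#'   and weight-update monitors.
#' @param max_neurons Maximum number of receptive fields to draw.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.snn_wta <- function(x, which = c("weights", "dynamics"),
                         max_neurons = 25, ...) {
  which <- match.arg(which)
  arch <- x$network$arch
  if (which == "weights") {
    n <- min(arch$n_exc, max_neurons)
    k <- ceiling(sqrt(n))
    op <- graphics::par(mfrow = c(k, k), mar = c(0.3, 0.3, 0.3, 0.3))
    on.exit(graphics::par(op))
    w <- x$network$w
    w[x$network$status == 2L] <- 0
    for (i in seq_len(n)) {
      m <- matrix(w[, i], arch$grid_h, arch$grid_w)
      graphics::image(t(m[arch$grid_h:1, ]), axes = FALSE,
                      col = grDevices::gray.colors(64, 0, 1))
    }
  } else {
    d <- x$dynamics
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    plot(d$window, d$mean_spike_count, type = "b", xlab = "window",
         ylab = "mean spike count")
    plot(d$window, d$mean_dw, type = "b", xlab = "window",
         ylab = "mean dw")
  }
  invisible(x)
}

#' Simulate spike responses of a fitted network
#'
#' Draws `nsim` independent Poisson rate-coded responses to the supplied
#' images with learning frozen.
#'
#' @param object An `snn_wta` fit.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param newdata Images to present.
#' @param ... Unused.
#' @return List of `nsim` spike-count matrices (images x neurons).
#' @export
simulate.snn_wta <- function(object, nsim = 1, seed = NULL,
                             newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(s)
    predict(object, newdata, type = "counts"))
}
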