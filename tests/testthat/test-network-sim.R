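test_that("Poisson encoding: zero rate, exact proportionality, Monte-Carlo mean", {
  set.seed(3)
  s <- encode_poisson(c(0, 255), duration = 50, max_rate = 100, dt = 0.5)
  expect_identical(sum(s[, 1]), 0L)  # zero-intensity pixel never spikes
  expect_error(encode_poisson(c(-1, 10), 10, 100), "intensities")
  expect_error(encode_poisson(c(10, 300), 10, 100), "intensities")

  # intensity 128 -> rate exactly (128/255) * max_rate; check via the
  # per-step Bernoulli probability over many trials
  r <- 100; T_ms <- 200; n_rep <- 200
  counts <- replicate(n_rep, sum(encode_poisson(c(128), T_ms, r, 0.5)))
  p <- (128 / 255) * r * 0.5 / 1000
  n_steps <- T_ms / 0.5
  expect_equal(mean(counts), n_steps * p,
               tolerance = 3 * sqrt(n_steps * p * (1 - p) / n_rep) /
                 (n_steps * p))

  # intensity 255: empirical mean within 3 standard errors of r*T
  counts255 <- replicate(n_rep, sum(encode_poisson(c(255), T_ms, r, 0.5)))
  expected <- n_steps * (r * 0.5 / 1000)
  se <- sqrt(n_steps * 0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(counts255) - expected), 3 * se)
})

test_that("WTA lateral matrices have the stated structure", {
  m <- wta_weight_matrices(5, 10.4, 17.0)
  expect_identical(diag(m$exc_inh), rep(10.4, 5))
  expect_true(all(m$exc_inh[upper.tri(m$exc_inh)] == 0))
  expect_identical(diag(m$inh_exc), rep(0, 5))
  off <- m$inh_exc[row(m$inh_exc) != col(m$inh_exc)]
  expect_true(all(off == 17.0))
})

test_that("blank image yields no input spikes and no accumulation SOPs", {
  set.seed(5)
  net <- new_snn_network(arch_config(4, 4, n_exc = 3))
  rec <- present_image(net, rep(0, 16), plastic = TRUE)
  expect_identical(rec$n_input_spikes, 0)
  expect_identical(ledger_summary(net)$train_accum, 0)
})

test_that("one input spike delivers one accumulation SOP per non-removed synapse", {
  # single step with p = 1 for unit 2 only; 1 removed, 1 frozen synapse
  net <- one_step_net(n_in = 4, n_exc = 3)
  net$status[2, 1] <- 2L  # removed
  net$status[2, 2] <- 1L  # frozen
  img <- c(0, 255, 0, 0)
  rec <- present_image(net, img, plastic = TRUE)
  expect_identical(rec$n_input_spikes, 1)
  l <- ledger_summary(net)
  expect_identical(l$train_accum, 2)      # frozen + active deliver
  expect_identical(l$train_stdp_pre, 1)   # only the active synapse updates
})

test_that("frozen run leaves weights, theta, and traces bit-identical", {
  set.seed(9)
  net <- new_snn_network(arch_config(4, 4, n_exc = 3))
  w0 <- net$w + 0; th0 <- net$theta + 0; x0 <- net$x + 0
  rec <- present_image(net, rep(200, 16), plastic = FALSE)
  expect_identical(net$w, w0)
  expect_identical(net$theta, th0)
  expect_identical(net$x, x0)
  expect_identical(ledger_summary(net)$train_stdp_pre, 0)
  expect_identical(ledger_summary(net)$images_infer, 1)
})

test_that("engine matches an R reference built from the module operations", {
  # deterministic drive (p = 1 on two units), single excitatory neuron so
  # the lateral loop is inert; compare after 40 steps
  n_steps <- 40
  arch <- arch_config(grid_h = 1, grid_w = 3, n_exc = 1,
                      present_ms = n_steps * 0.5, rest_ms = 0,
                      max_rate_hz = 2000, w_inh_exc = 0)
  np <- neuron_params()
  pp <- plasticity_params(norm_frac = 0)  # normalization off: pure STDP
  set.seed(21)
  net <- new_snn_network(arch, np, inhibitory_params(), pp)
  w0 <- net$w + 0
  img <- c(255, 255, 0)
  rec <- present_image(net, img, plastic = TRUE)

  # R reference: compose step_neurons / decay_traces / stdp ops in the
  # engine's event order
  bank <- synapse_bank(w0, w_max = pp$w_max)
  tr <- trace_state(3, 1)
  st <- neuron_state(1, np)
  spikes <- 0L
  for (t in seq_len(n_steps)) {
    drive <- sum(bank$w[1:2, 1])  # both units spike every step
    out <- step_neurons(st, np, exc_input = drive, inh_input = 0, dt = 0.5)
    st <- out$state
    tr <- decay_traces(tr, 0.5, pp)
    for (j in 1:2) {
      upd <- stdp_on_pre(bank, tr, j, pp)
      # defer the x reset until after potentiation (engine order)
      upd$traces$x[j] <- tr$x[j]
      bank <- upd$bank; tr <- upd$traces
    }
    if (out$fired) {
      upd <- stdp_on_post(bank, tr, 1, pp)
      bank <- upd$bank; tr <- upd$traces
      spikes <- spikes + 1L
    }
    tr$x[1:2] <- 1
  }
  expect_equal(rec$counts[1], spikes)
  expect_equal(net$w, bank$w, tolerance = 1e-12)
  expect_equal(net$v_exc, st$v, tolerance = 1e-12)
  expect_equal(net$y1, tr$y1, tolerance = 1e-12)
  expect_equal(net$x, tr$x, tolerance = 1e-12)
})

test_that("with zero inhibitory weight, neurons evolve as in isolation", {
  arch_full <- arch_config(4, 4, n_exc = 3, w_inh_exc = 0)
  set.seed(31)
  net_full <- new_snn_network(arch_full)
  w_full <- net_full$w + 0
  img <- c(rep(230, 8), rep(0, 8))
  set.seed(77)
  rec_full <- present_image(net_full, img, plastic = FALSE)
  for (i in 1:3) {
    arch_one <- arch_config(4, 4, n_exc = 1, w_inh_exc = 0)
    net_one <- new_snn_network(arch_one)
    net_one$w <- w_full[, i, drop = FALSE]
    set.seed(77)  # same encoding stream
    rec_one <- present_image(net_one, img, plastic = FALSE)
    expect_identical(rec_one$counts[1], rec_full$counts[i])
    expect_identical(net_one$v_exc, net_full$v_exc[i])
  }
})

test_that("same seed and config reproduce a run bit-identically", {
  d <- make_synthetic(synthetic_spec(seed = 4), 30, 5)
  run <- function() train_snn(d$train, arch = desk_arch(5),
                              monitor_window = 10, seed = 123)
  f1 <- run(); f2 <- run()
  expect_identical(f1$network$w, f2$network$w)
  expect_identical(f1$network$theta, f2$network$theta)
  expect_identical(f1$spike_counts, f2$spike_counts)
  expect_identical(ledger_summary(f1), ledger_summary(f2))
})

test_that("training dynamics windows reproduce direct moment computation", {
  dw <- c(0.1, -0.2, 0.05, 0, 0.3, -0.1)
  # pack the six updates into two images
  log <- rbind(c(3, sum(dw[1:3]), sum(dw[1:3]^2)),
               c(3, sum(dw[4:6]), sum(dw[4:6]^2)))
  spikes <- rbind(c(2L, 0L), c(1L, 3L))
  dyn <- compute_training_dynamics(log, spikes, window = 2)
  expect_equal(dyn$mean_dw, mean(dw))
  expect_equal(dyn$var_dw, mean(dw^2) - mean(dw)^2)
  expect_equal(dyn$mean_spike_count, mean(spikes))
  # empty window is flagged with NA moments and zero counts
  dyn0 <- compute_training_dynamics(matrix(0, 2, 3), matrix(0L, 2, 2),
                                    window = 2)
  expect_true(dyn0$empty)
  expect_identical(dyn0$mean_spike_count, 0)
  expect_true(is.na(dyn0$mean_dw))
})

test_that("label assignment is a row-wise argmax with stated tie-breaks", {
  # brute-force oracle on a random count matrix
  set.seed(13)
  counts <- matrix(rpois(15, 4), 5, 3)
  a <- assignment_from_counts(counts, classes = 0:2)
  oracle <- apply(counts, 1, function(r) (0:2)[which(r == max(r))[1]])
  expect_identical(a$neuron_labels, oracle)
  # tie goes to the lowest class
  a2 <- assignment_from_counts(rbind(c(5, 5, 2)), classes = 0:2)
  expect_identical(a2$neuron_labels, 0L)
  # silent neuron gets the first class and is flagged
  a3 <- assignment_from_counts(rbind(c(0, 0, 0), c(0, 1, 0)), classes = 0:2)
  expect_identical(a3$neuron_labels[1], 0L)
  expect_true(a3$silent[1])
  expect_false(a3$silent[2])
})

test_that("classification uses group means, excludes empty groups, flags silence", {
  a <- assignment_from_counts(rbind(c(9, 0), c(8, 0), c(0, 5)),
                              classes = c("A", "B"))
  # groups: A = {1, 2}, B = {3}; counts (2, 4, 5): mean A = 3, mean B = 5
  expect_identical(as.character(classify(c(2, 4, 5), a)), "B")
  # only one group fires
  expect_identical(as.character(classify(c(3, 3, 0), a)), "A")
  # all groups silent -> first class, flagged
  p <- classify(c(0, 0, 0), a)
  expect_identical(as.character(p), "A")
  expect_true(attr(p, "no_signal"))
})

test_that("an untrained network carries no learned class structure", {
  # an untrained random net still classifies somewhat above chance here:
  # random projections of well-separated sparse prototypes are weakly
  # informative.  Training must beat it clearly, and once the neuron
  # labels are shuffled the untrained net must fall to chance (binomial
  # 99% CI).
  d <- desk_data()
  set.seed(55)
  net <- new_snn_network(desk_arch())
  fit <- structure(list(network = net, spike_counts = matrix(0L, 0, 30),
                        prune = prune_config("none"), seed = 55,
                        prune_log = data.frame(), dynamics = NULL),
                   class = "snn_wta")
  fit$assignment <- assign_labels(net, d$train$images[1:90, , ],
                                  d$train$labels[1:90])
  labels <- d$test$labels[1:120]
  preds <- predict(fit, d$test$images[1:120, , ], seed = 6)
  acc_untrained <- mean(preds == labels)
  trained <- baseline_fit()
  acc_trained <- evaluate_accuracy(trained, d$test, seed = 6)
  expect_gt(acc_trained, acc_untrained)

  # permutation null: with the predictions fixed and balanced test labels
  # randomly permuted, accuracy must sit at chance
  set.seed(8)
  acc_perm <- mean(replicate(200, mean(preds == sample(labels))))
  expect_lt(abs(acc_perm - 1 / 3), 0.03)
})
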