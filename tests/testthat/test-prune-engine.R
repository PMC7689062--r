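test_that("time schedules match their closed forms and are clamped", {
  s1 <- time_schedule("f1", wth0 = 0.036, factor = 1.3)
  expect_equal(eval_time_threshold(s1, 2), 0.06084)
  expect_equal(eval_time_threshold(s1, 0), 0.036)
  # unit base is exactly constant
  s1n <- time_schedule("f1", wth0 = 0.036, factor = 1)
  expect_identical(eval_time_threshold(s1n, 17), 0.036)
  s3 <- time_schedule("f3", wth0 = 0.02, factor = 0.01)
  expect_identical(eval_time_threshold(s3, 0), 0.02)
  expect_equal(eval_time_threshold(s3, 5), 0.07)
  # cap at w_max
  expect_identical(eval_time_threshold(s1, 50), 1)
  s2 <- time_schedule("f2", wth0 = 0.036, factor = 1.1, w_max = 1)
  expect_equal(eval_time_threshold(s2, 3), 1 - (1 - 0.036) * 1.1^-3)
  expect_error(time_schedule("f1", factor = -1), "factor")
  expect_error(eval_time_threshold(s1, -1), "k")
})

test_that("batch spike counts average per image and per neuron", {
  expect_identical(compute_batch_spike_counts(matrix(0L, 5, 3)),
                   c(0, 0, 0))
  expect_identical(compute_batch_spike_counts(matrix(1L, 4, 2)), c(1, 1))
  set.seed(2)
  m <- matrix(rpois(20, 3), 5, 4)
  expect_equal(compute_batch_spike_counts(m),
               apply(m, 2, function(col) sum(col) / length(col)))
})

test_that("grouping follows the interval rule", {
  # worked partition: counts {0, 10, 40, 100} at SI = 30
  p <- group_neurons(c(0, 10, 40, 100), SI = 30)
  expect_length(p, 3)
  expect_identical(p[[1]]$members, c(1L, 2L))
  expect_identical(p[[2]]$members, 3L)
  expect_identical(p[[3]]$members, 4L)
  expect_identical(vapply(p, `[[`, numeric(1), "S"), c(0, 40, 100))
  # all equal -> one group; SI = Inf -> one group
  expect_length(group_neurons(rep(4.2, 7), SI = 1), 1)
  expect_length(group_neurons(c(0, 5, 500, 1e4), SI = Inf), 1)
  # membership inclusive at S + SI
  p2 <- group_neurons(c(0, 30, 31), SI = 30)
  expect_identical(p2[[1]]$members, c(1L, 2L))
  expect_identical(p2[[2]]$members, 3L)
})

test_that("grouping invariants hold on randomized inputs", {
  set.seed(8)
  for (rep in 1:20) {
    counts <- rpois(40, lambda = sample(c(2, 20, 80), 1)) +
      runif(40, 0, 5)
    SI <- sample(c(5, 30, 100), 1)
    p <- group_neurons(counts, SI)
    members <- unlist(lapply(p, `[[`, "members"))
    expect_identical(sort(members), 1:40)        # partition
    spread <- vapply(p, function(g) diff(range(counts[g$members])),
                     numeric(1))
    expect_true(all(spread <= SI))               # within-group range <= SI
    mins <- vapply(p, `[[`, numeric(1), "S")
    expect_true(all(diff(mins) > 0))             # strictly increasing minima
  }
})

test_that("group thresholds start at the base and adapt per family", {
  p <- group_neurons(c(0, 10, 40, 100), SI = 30)  # 3 groups
  thr <- assign_group_thresholds(p, base = 0.02, kind = "f1", factor = 1.15)
  expect_identical(thr$per_group[1], 0.02)
  expect_equal(thr$per_group, c(0.02, 0.023, 0.02645))
  # broadcast to members
  expect_equal(thr$per_neuron, c(0.02, 0.02, 0.023, 0.02645))
  # neutral factor shares the base exactly
  thr1 <- assign_group_thresholds(p, base = 0.037, kind = "f1", factor = 1)
  expect_identical(thr1$per_group, rep(0.037, 3))
  thr2 <- assign_group_thresholds(p, base = 0.037, kind = "f2", factor = 1)
  expect_identical(thr2$per_group, rep(0.037, 3))
  # non-decreasing in group index for factor >= 1 / f3 with c >= 0
  thr3 <- assign_group_thresholds(p, base = 0.05, kind = "f3", factor = 0.01)
  expect_true(all(diff(thr3$per_group) >= 0))
  expect_true(all(diff(thr$per_group) >= 0))
  # cap at w_max
  thr4 <- assign_group_thresholds(p, base = 0.9, kind = "f1", factor = 2,
                                  w_max = 1)
  expect_identical(thr4$per_group[3], 1)
})

test_that("prune_batch removes strictly sub-threshold active synapses", {
  w <- matrix(c(0.1, 0.3, 0.0, 0.5, 0.02, 0.9), 3, 2)
  bank <- synapse_bank(w)
  out <- prune_batch(bank, thresholds = c(0.2, 0.2), method = "constant")
  # brute-force comparison over all six entries
  expect_identical(out$bank$status,
                   matrix(as.integer(w < 0.2) * 2L, 3, 2))
  expect_identical(out$n_new, 3L)
  # weights are retained, not zeroed
  expect_identical(out$bank$w, w)
  # threshold 0 prunes nothing (strict comparison, weights >= 0)
  expect_identical(prune_batch(synapse_bank(w), 0)$n_new, 0L)
  # second call with the same thresholds prunes nothing new
  expect_identical(prune_batch(out$bank, c(0.2, 0.2))$n_new, 0L)
  # a weight exactly at threshold survives
  expect_identical(prune_batch(synapse_bank(matrix(0.2, 1, 1)), 0.2)$n_new,
                   0L)
  # soft method freezes instead of removing
  soft <- prune_batch(synapse_bank(w), c(0.2, 0.2), method = "soft")
  expect_identical(soft$bank$status,
                   matrix(as.integer(w < 0.2) * 1L, 3, 2))
  # losing every synapse of a neuron warns
  expect_warning(prune_batch(synapse_bank(w), c(1, 0)), "lost all")
})

test_that("connectivity and unpruned fraction count statuses", {
  bank <- synapse_bank(matrix(0.5, 2, 3))
  expect_identical(connectivity(bank), 1)
  bank$status[1, 1:2] <- 2L
  expect_equal(connectivity(bank), 4 / 6)
  bank$status[2, 1] <- 1L  # frozen still counts as connected
  expect_equal(connectivity(bank), 4 / 6)
  expect_equal(unpruned_fraction(bank), 3 / 6)
  bank$status[] <- 2L
  expect_identical(connectivity(bank), 0)
})

test_that("neutral-factor APT/APN/APTN reproduce constant pruning bit-for-bit", {
  d <- desk_data()
  x <- d$train$images[1:700, , ]
  lab <- d$train$labels[1:700]
  run <- function(prune) {
    suppressWarnings(train_snn(x, lab, arch = desk_arch(10), prune = prune,
                               monitor_window = 350, seed = 17,
                               assign = FALSE))
  }
  base <- run(prune_config("constant", wth0 = 0.05, t_m = 300, batch = 100))
  neutral <- list(
    prune_config("APT", wth0 = 0.05, time_factor = 1, t_m = 300, batch = 100),
    prune_config("APN", wth0 = 0.05, neuron_factor = 1, SI = Inf,
                 t_m = 300, batch = 100),
    prune_config("APTN", wth0 = 0.05, time_factor = 1, neuron_factor = 1,
                 SI = Inf, t_m = 300, batch = 100),
    prune_config("APT", wth0 = 0.05, time_kind = "f2", time_factor = 1,
                 t_m = 300, batch = 100),
    prune_config("APT", wth0 = 0.05, time_kind = "f3", time_factor = 0,
                 t_m = 300, batch = 100))
  for (pr in neutral) {
    f <- run(pr)
    expect_identical(f$network$w, base$network$w)
    expect_identical(f$network$status, base$network$status)
    expect_identical(f$spike_counts, base$spike_counts)
    expect_identical(f$prune_log$connectivity, base$prune_log$connectivity)
  }
})

test_that("SI = Inf reduces APN to APT exactly", {
  d <- desk_data()
  x <- d$train$images[1:600, , ]
  run <- function(prune)
    suppressWarnings(train_snn(x, arch = desk_arch(10), prune = prune,
                               monitor_window = 300, seed = 19,
                               assign = FALSE))
  apn <- run(prune_config("APN", wth0 = 0.05, neuron_factor = 1.15,
                          SI = Inf, t_m = 300, batch = 100))
  apt_like <- run(prune_config("APN", wth0 = 0.05, neuron_factor = 1.15,
                               SI = 1e9, t_m = 300, batch = 100))
  expect_identical(apn$network$w, apt_like$network$w)
  expect_identical(apn$network$status, apt_like$network$status)
  # one group at every step
  expect_true(all(apn$prune_log$n_groups == 1))
})

test_that("soft pruning freezes weights at their values and removes nothing", {
  d <- desk_data()
  x <- d$train$images[1:900, , ]
  fit <- suppressWarnings(train_snn(x, arch = desk_arch(10),
                                    prune = prune_config("soft", wth0 = 0.06,
                                                         t_m = 300,
                                                         batch = 100),
                                    monitor_window = 300, seed = 23,
                                    assign = FALSE))
  expect_identical(connectivity(fit), 1)          # no removal
  expect_lt(unpruned_fraction(fit), 1)            # but synapses froze
  net <- fit$network
  frozen <- net$status == 1L
  w_frozen <- net$w[frozen]
  # continue training: frozen weights must not move
  for (m in 851:900) present_image(net, x[m, , ], plastic = TRUE)
  expect_identical(net$w[frozen], w_frozen)
})

test_that("connectivity never increases across pruning steps", {
  d <- desk_data()
  x <- d$train$images[1:800, , ]
  for (method in c("constant", "APT", "APTN")) {
    fit <- suppressWarnings(train_snn(
      x, arch = desk_arch(10),
      prune = prune_config(method, wth0 = 0.08, t_m = 300, batch = 100),
      monitor_window = 400, seed = 29, assign = FALSE))
    expect_true(all(diff(fit$prune_log$connectivity) <= 0))
  }
})

test_that("post-training pruning leaves training SOPs untouched", {
  d <- desk_data()
  x <- d$train$images[1:300, , ]
  lab <- d$train$labels[1:300]
  unpruned <- train_snn(x, lab, arch = desk_arch(10), monitor_window = 150,
                        seed = 31, assign = FALSE)
  post <- suppressWarnings(train_snn(
    x, lab, arch = desk_arch(10),
    prune = prune_config("post_training", wth0 = 0.08),
    monitor_window = 150, seed = 31, assign = FALSE))
  expect_identical(sops_per_image(unpruned, "train"),
                   sops_per_image(post, "train"))
  expect_lt(connectivity(post), 1)
  expect_identical(nrow(post$prune_log), 1L)
})
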