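# snnprune

Unsupervised spiking neural networks (SNNs) learn image categories with
spike-timing-dependent plasticity (STDP), but a fully connected network
carries far more synapses than it needs, and on neuromorphic hardware
every synaptic event costs energy.  `snnprune` implements a two-layer
winner-take-all (WTA) SNN — Poisson rate-coded inputs, conductance-based
leaky integrate-and-fire neurons with adaptive thresholds, triplet STDP —
together with an *online adaptive weight pruning* method that removes
weak synapses **while the network trains**, adapting the pruning
threshold both over time and over neurons:

* over **time**: the threshold starts low (so half-trained weights are
  spared) and grows across pruning steps, e.g. exponentially,
  `wth(k) = wth0 * a^k`, confined to `[wth0, w_max]`;
* over **neurons**: at each pruning step neurons are grouped by their
  batch-average firing rate (groups span at most `SI` spikes); the weakest
  group keeps the lowest threshold, so weakly connected neurons are not
  destroyed by a threshold calibrated for strong ones.

The combination (APTN) is compared against constant-threshold, soft
(freeze-instead-of-remove), and post-training pruning baselines.  The
package also does the cost accounting that motivates pruning: synaptic
operations (SOPs) per image during training and inference, a figure of
merit `FOM = accuracy loss x normalized total SOPs/image` for choosing
the operating connectivity, and first-order hardware-overhead estimates
(clock cycles, operations, energy, NAND-gate area) for the pruning unit
itself.

The package is aimed at computational-neuroscience and neuromorphic
researchers who want a reproducible, testable reference implementation of
pruning-while-training in unsupervised SNNs at desk scale, with support
for full-scale MNIST-format (IDX/ubyte) datasets.

## Worked example

Train on the built-in synthetic task (3 classes of sparse bright blobs on
a 16x16 grid, rate-coded into Poisson spike trains), pruning online with
APTN, then evaluate:

```r
library(snnprune)

d <- make_synthetic(synthetic_spec(), n_train = 3000, n_test = 300)
arch <- arch_config(16, 16, n_exc = 30)

base <- train_snn(d$train, arch = arch, seed = 207, monitor_window = 500)
aptn <- train_snn(d$train, arch = arch, seed = 207, monitor_window = 500,
                  prune = prune_config("APTN", wth0 = 0.08,
                                       t_m = 1500, batch = 250))
aptn
#> Unsupervised WTA spiking network
#>   input 16 x 16 (256 units) -> 30 excitatory / 30 inhibitory
#>   trained on 3000 image presentations (seed 207)
#>   pruning: APTN; connectivity 12.1%
#>   labels assigned over 3 classes

evaluate_accuracy(base, d$test, seed = 99)
#> [1] 1
evaluate_accuracy(aptn, d$test, seed = 99)
#> [1] 1
normalized_reduction(aptn, base)
#> $train_pct
#> [1] 29.2744
#> $infer_pct
#> [1] 86.68405
```

Here pruning to ~12% connectivity removed 29% of training SOPs/image and
87% of inference SOPs/image at no accuracy cost (this easy,
well-separated synthetic task saturates; on harder data accuracy
degrades gracefully with sparsity and the FOM picks the operating
point).  `plot(aptn)` draws the learned receptive fields;
`summary(aptn)`, `coef(aptn)`, `predict(aptn, newdata)` and
`simulate(aptn, newdata = ...)` behave as for other fitted-model objects.

Hardware-overhead estimates for the full-scale 784-input, 100-neuron
network:

```r
estimate_pruning_overhead(784, 100)$per_batch
#>            phase cycles    ops
#> 1       grouping    120    400
#> 2       adapting   2000   1100
#> 3 weight_pruning  78400 156800
estimate_energy(96099, 18)$sop_energy_uJ   # ~2.3 uJ per image
#> [1] 2.267936
100 * gate_ratio()                         # pruning unit vs SNN core, %
#> [1] 0.2761333
```

A thin command-line front end is installed at
`inst/cli/snnprune.R` (`train`, `prune-sweep`, `evaluate`, `overhead`,
`prestart-scan`); the `run_*()` functions it wraps are the programmatic
interface, and `experiment_config(dataset = list(type = "idx", ...))`
points them at MNIST-format `*-idx3-ubyte` files for full-scale runs.

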