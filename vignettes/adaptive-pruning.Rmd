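---
title: "Adaptive online weight pruning in unsupervised spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive online weight pruning in unsupervised spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`snnprune` simulates a two-layer spiking network that learns image
categories without labels and, while it learns, removes the synapses it
can do without.  The input layer contains one Poisson unit per pixel,
firing at a rate proportional to pixel intensity (rate coding, with
`max_rate_hz` at intensity 255).  It is fully connected, with plastic
weights, to a winner-take-all (WTA) layer of `n_exc` excitatory
conductance-based leaky integrate-and-fire neurons:

$$\tau_m \frac{dv}{dt} = (v_r - v) - g_e\,(v - E_{exc}) - g_i\,(v - E_{inh}),$$

where the conductances decay as $\tau_g\,dg/dt = -g$ and jump by the
synaptic weight at each presynaptic spike.  A neuron fires when
$v \ge v_{th} + \theta$, resets to $v_r$, and increments its adaptive
threshold $\theta$ by a small constant (0.01 mV); $\theta$ decays slowly,
which homeostatically shares activity across the population.  Each
excitatory neuron drives one inhibitory partner, and each inhibitory
neuron inhibits every excitatory neuron except its source — the lateral
inhibition that makes neurons compete for input features.

Plasticity is the triplet form of spike-timing-dependent plasticity
(STDP).  Each input unit carries a trace $x_j$ and each excitatory neuron
two traces $y_i^1$ (fast) and $y_i^2$ (slow); every trace decays
exponentially and is reset to 1 when its owner fires.  A presynaptic
spike depresses the synapse by $\mu_{pre}\,y_i^1$; a postsynaptic spike
potentiates it by $\mu_{post}\,x_j\,y_i^2$, with $y_i^2$ taken just
before its own reset.  Weights are clipped to $[0, w_{max}]$.

After training, each excitatory neuron is labeled with the class for
which it fired most during a plasticity-frozen assignment pass, and a
test image is classified by the label group with the highest mean spike
count.

## Online adaptive pruning

Pruning acts only on the plastic input projection.  After `t_m` training
images, and then at every `batch`-image boundary, every active synapse
whose weight falls strictly below its neuron's threshold is removed —
permanently: a removed synapse neither transmits nor learns.  The
threshold is not constant:

* **Over time (APT).**  The global threshold starts at `wth0` and grows
  with the pruning-step index $k$ via one of three families:
  $f_1 = w_{th}^0\,a^k$ (slow first, fast later),
  $f_2 = w_{max} - (w_{max} - w_{th}^0)\,b^{-k}$ (fast first, saturating),
  or the linear $f_3 = w_{th}^0 + c\,k$.  All values are confined to
  $[w_{th}^0, w_{max}]$; keeping the threshold below $w_{max}$ means the
  schedule can never prune the entire network.  A gentle start avoids
  removing weights that have not yet been trained; a steep end enforces
  sparsity once learning has stabilized.
* **Over neurons (APN).**  Neurons differ in how strongly they are
  connected to the input, which their firing rate reflects.  At each
  pruning step the neurons are grouped by batch-average spike count:
  starting from the minimum count $S$ of the ungrouped neurons, all
  neurons within $[S, S + SI]$ form a group (inclusive at both ends), and
  so on — so the within-group spread never exceeds the spike-count
  interval $SI$, and $SI = \infty$ yields a single group.  The global
  threshold is assigned to the weakest group G0 and adapted upward across
  groups with the same function families, so weak neurons keep more of
  their synapses.
* **APTN** combines both: group, adapt across groups from the current
  global threshold, prune, then advance the global threshold in time.

Two baselines are built in: *constant* pruning (fixed threshold, one
group — exactly what any family degenerates to at a neutral factor
$a=1$, $b=1$, or $c=0$, and the package short-circuits neutral factors so
the equivalence is bit-exact), *soft* pruning (sub-threshold weights are
frozen at their current value: they still transmit, never learn, and
induce no sparsity), and *post-training* pruning (one uniform prune after
the pass, leaving training cost untouched).

## Cost accounting

The energy of neuromorphic hardware is dominated by synaptic operations
(SOPs).  The ledger counts one accumulation per presynaptic spike
delivered across each non-removed synapse and one STDP update per
performed weight modification on an active synapse (a clipped
zero-magnitude update still counts — the hardware executes it; frozen
synapses accumulate but never update).  Training SOPs/image are
accumulations plus STDP updates; inference counts accumulations only.
Fixed lateral (exc→inh, inh→exc) events are tallied separately and
excluded from reduction percentages, since pruning cannot affect them.
The figure of merit $FOM = \text{accuracy loss (pp)} \times
\text{normalized total SOPs/image}$ selects a connectivity that balances
accuracy against remaining cost.  The overhead estimator prices the
pruning unit itself — per batch, grouping and threshold adaptation use
fixed cycle/operation budgets (assuming at most 20 groups and no
parallelism), while the weight-pruning phase touches every synapse once
through a single memory port: $n_{in} n_{exc}$ cycles and
$2\,n_{in} n_{exc}$ operations — and converts operation counts to energy
at 23.6 pJ/SOP and 0.5 pJ per memory access (every pruning operation
costed as an access, the worst case).

## Numerical scheme and event order

The simulation is clock-driven with explicit Euler for the membrane at
`dt = 0.5` ms — half the smallest conductance time constant
($\tau_{ge} = 1$ ms); conductances and traces use exact exponential decay
factors, so inter-spike decay is accurate to machine precision and only
the membrane carries the $O(dt)$ Euler error.  Within a step the order
is: conductance decay → spike delivery (input spikes of this step,
lateral spikes of the previous step, i.e. lateral events carry one step
of delay) → membrane update and spike detection → trace decay →
depression for presynaptic spikes → potentiation for postsynaptic spikes
(pre-reset $y^2$) → trace resets.  Simultaneous pre/post spikes therefore
both apply their updates.  Input spikes are pre-drawn per image by
geometric gap sampling, which reproduces the per-step Bernoulli coding
exactly with far fewer random draws; the presynaptic trace is evaluated
lazily from its last reset time, which is exact because it always resets
to 1.  All randomness flows through R's RNG, so a run is bit-identical
under the same seed and configuration.  Non-finite neuron state aborts
the run.

Degenerate cases are fixed deliberately: pruning compares strictly
(`w < threshold`, so a zero threshold removes nothing), group membership
is inclusive at both interval ends, classification ties go to the lowest
class index, a neuron silent on every class is assigned the first class
and flagged, and a warning is emitted if a neuron loses its last synapse
(the threshold cap at $w_{max}$ is the only global guard).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| $\tau_m, \tau_{ge}, \tau_{gi}$ | 100, 1, 2 ms | excitatory LIF time constants |
| $v_r, v_{th}, E_{exc}, E_{inh}$ | −60, −50, 0, −100 mV | LIF potentials |
| $\tau_x, \tau_{y1}, \tau_{y2}$ | 8, 16, 32 ms | triplet STDP traces |
| $\mu_{pre}, \mu_{post}$ | 0.0001, 0.01 | STDP rates |
| $\theta_+$ | 0.01 mV | threshold adaptation increment |
| $\tau_\theta$ | $10^5$ ms | threshold decay; slow relative to one 0.5 s presentation |
| `t_refrac` | 0 ms | refractory period |
| $w_{max}$ | 1.0 | weight cap; init uniform on $[0, 0.3\,w_{max}]$ |
| `norm_frac` | 0.1 | per-neuron total active input weight, as a fraction of $n_{in} w_{max}$ |
| `present_ms`, `rest_ms` | 350, 150 ms | presentation and silent period |
| `max_rate_hz` | 63.75 | Poisson rate at intensity 255 |
| `w_exc_inh`, `w_inh_exc` | 10.4, 17.0 | fixed WTA weights |
| pruning | f1, $a$=1.3 (time), f1, $a$=1.15 (neurons), SI=30, $t_m$=30,000, batch=5,000 | reported selections for the 100-neuron network ($a$=1.2 over time for 800 neurons) |

Presentation timing, input rate scaling, and the fixed WTA weights follow
the conventions of the classic unsupervised WTA digit architecture this
network mirrors; they are configurable, not canonical.  Three choices
deserve justification:

* **Inhibitory neuron parameters.**  With the excitatory constants
  ($\tau_m = 100$ ms) a single `w_exc_inh` conductance kick decays
  ($\tau_{ge} = 1$ ms) long before it can drive a relay neuron the 10 mV
  from rest to threshold, so the one-to-one relay would be silent.  The
  inhibitory population therefore defaults to the classic relay values
  $\tau_m = 10$ ms, $v_{th} = -40$ mV, $v_r = -60$ mV, with no threshold
  adaptation (`inhibitory_params()`), and fires reliably per excitatory
  spike.
* **Weight normalization.**  After each training image the active input
  weights of each neuron are divisively rescaled to the fixed total
  `norm_frac * n_input * w_max`.  Without it, competition degenerates: a
  few early winners potentiate every frequently active pixel (noise
  included), saturate their entire weight vector, and selectivity
  collapses to chance — we observed exactly this on the synthetic task.
  Normalization is the standard homeostatic companion of this
  architecture.  Frozen and removed synapses are excluded, so soft/hard
  pruning immutability is preserved; the rescaling is not an SOP and does
  not enter the weight-update monitors.
* **Threshold decay form.**  The adaptive threshold decays exponentially
  with $\tau_\theta$ (a linear decay would need an extra clamp at zero);
  $\tau_\theta$ defaults to $10^5$ ms so that $\theta$ is quasi-static
  within one presentation but relaxes over thousands of images.

## The synthetic generator

`make_synthetic()` emulates the features of digit data this network
exploits: a small number of distinct sparse prototypes (per class, three
3×3 bright blobs on a 16×16 grid, drawn without replacement from a
disjoint block partition so classes never overlap), per-pixel Gaussian
noise (sd 20, clipped to [0, 255]), and intensity-proportional firing.
It does **not** reproduce stroke-like correlated structure, within-class
shape variability, or class overlap, so desk-scale results are a sanity
check of the machinery, not a forecast of image-benchmark accuracy.  Two
consequences matter when reading the tests: a *random untrained* network
already classifies somewhat above chance here (random projections of
well-separated prototypes are informative), and pruned networks can
*exceed* the unpruned baseline (pruning acts as denoising), so accuracy
losses can be negative and the accuracy ceiling compresses differences
between pruning methods that are visible on harder data only at extreme
sparsity.

## Desk-scale study conditions

The package's tests and the acceptance script run a scaled-down version
of the full study: 30 excitatory neurons, 3 classes, 3,000 training and
300 test images, with pruning starting after 1,500 images in 250-image
batches — the same 1:2 pre-pruning ratio and 1:12 batch ratio as the
full-scale 30,000/5,000-of-60,000 protocol.  Label assignment uses the
full training set (the default).  A full-scale run on MNIST-format files
is supported through `read_idx()` and `experiment_config(dataset =
list(type = "idx", ...))` but takes hours on one CPU and is not part of
the test suite.

## Known limitations

* Single plastic projection; no deep or recurrent extensions.
* No axonal delays beyond the one-step lateral delivery; no
  multi-compartment neurons.
* Hardware numbers are first-order estimates (operation counts times
  per-operation energies), not a cycle-accurate simulation, and neural
  state-update energy is not modeled.
* Hyperparameters are taken as given, not re-optimized; no
  genetic-algorithm search is included.
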