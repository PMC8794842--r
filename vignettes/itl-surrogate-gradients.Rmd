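---
title: "In-the-loop surrogate-gradient training on an emulated analog substrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-the-loop surrogate-gradient training on an emulated analog substrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnitl)
```

## The problem

Analog neuromorphic processors emulate leaky integrate-and-fire (LIF)
neurons with physical circuits. They are fast and energy-efficient, but two
properties make them hard to train: the spike nonlinearity has no useful
derivative, and every fabricated neuron deviates from its design targets
(fixed-pattern mismatch), so a software model of the chip is always wrong in
detail. `snnitl` implements the in-the-loop (ITL) answer to both problems
and replaces the physical chip with a configurable simulated substrate, so
the whole training loop runs on a desktop: the forward pass is *emulated*
(heterogeneous neurons, trial noise, quantized weights, sampled readout),
observables are recorded, and the backward pass runs on an idealized
differentiable model into which the recordings are injected.

## Model

The substrate consists of a spiking hidden layer and a non-spiking readout
layer of leaky integrators. In the dimensionless convention (leak potential
0, capacitance 1, threshold $\vartheta = 1$), each hidden neuron obeys

$$\dot V = -V/\tau_m + I, \qquad \dot I = -I/\tau_s + \textstyle\sum_j w_j S_j(t),$$

with a spike emitted and the membrane reset when $V \ge \vartheta$. The
computation graph discretizes these dynamics on the readout sampling grid
$\Delta t$:

$$\tilde V[t+1] = \tilde V[t]\,e^{-\Delta t/\tau_m} + \tilde I[t], \qquad
  \tilde I[t+1] = \tilde I[t]\,e^{-\Delta t/\tau_s} + \sum_j W_j \tilde S_j[t],$$

optionally augmented with a recurrent term (one-bin delay). Two identity
functions make the emulated network differentiable:

* **Trace injection** — `inject_value(measured, modeled)` returns the
  measured value in the forward direction while the backward pass sends the
  entire upstream gradient to the model estimate. Recorded membranes replace
  $\tilde V$, and recorded spikes replace $\tilde S$, wherever they are
  available; only unobserved quantities (synaptic currents) rely on the
  model.
* **Surrogate derivative** — the spike nonlinearity's derivative is
  replaced by a pseudo-derivative evaluated *on the recorded membrane*. The
  default form is $(1 + \beta\,|\tilde V - \vartheta|)^{-2}$, which is
  bounded in $(0, 1]$; the unregularized form $(\beta\,|\tilde V -
  \vartheta|)^{-2}$ diverges at the threshold and is available
  (`surrogate_spec(form = "literal")`) with an $\varepsilon$ floor and is
  meant to be combined with gradient clipping. Forward values never depend
  on $\beta$.

BPTT through this graph (`unroll()`, compiled in C++) yields gradients for
the input, recurrent and output weight matrices; Adam updates a float
master copy, which is re-quantized and redeployed before every batch — the
substrate only ever sees 7-bit signed integers in $[-63, 63]$. Hidden-layer
synapses use a fixed scale (63 divided by a configurable software weight
maximum); the non-spiking readout uses a dynamic scale that maps the
largest absolute output weight to 63, which makes the deployed readout
invariant to a rescaling of the software weights.

## The emulated substrate

`substrate()` draws fixed-pattern mismatch once per instance:
`decalibrate()` replaces each selected parameter ($\tau_m$, $\tau_s$,
$\vartheta$) by a draw from a normal distribution centred on the
calibration target with SD $\sigma_d$ times the target. Time constants are
redrawn until positive; thresholds are not, so at large $\sigma_d$ some
neurons end up with thresholds at or below the leak potential and fire
without input ("leak-over-threshold", flagged by `leak_over_threshold()`).
Trial noise is additive Gaussian: a membrane diffusion term (SD per
$\sqrt{\Delta t}$) inside the dynamics and readout jitter on the sampled
traces, both defaulting to 1% of the threshold; setting both to zero makes
the substrate deterministic.

The integrator works on a fine step $\delta = \Delta t / F$
(`fine_factor`, default 10) with an exact exponential propagator and a
per-neuron coupling correction chosen so that, for inputs aligned to the
sampling bins, the membrane values *at sampling boundaries* coincide with
the coarse-grid model recursion for any $F$ — the fine trajectory is a
continuous-time interpolation consistent with the coarse map. This gives a
closed form for the postsynaptic potential,
$V(t) = w\,(e^{-t/\tau_m} - e^{-t/\tau_s})/(\lambda_m - \lambda_s)$ with
$\lambda_x = e^{-\Delta t/\tau_x}$, which the tests use as an independent
oracle, together with the analytic constant-drive firing period
$\tau_m \ln(I_0\tau_m / (I_0\tau_m - \vartheta))$. Spike detection and
reset happen at the fine step, so with $F > 1$ the device can emit spikes
between sampling points — exactly the regime in which the coarse graph is
only an approximation and trace injection earns its keep. With $F = 1$ the
comparator is clocked on the sampling grid and an ideal, noiseless,
unquantized substrate reproduces the graph's own dynamics bit for bit; this
is the configuration under which the package asserts that ITL gradients
equal pure-software surrogate gradients, and it is also the default in the
experiment configurations, where it keeps multi-run sweeps fast without
changing any of the studied effects (mismatch, noise, quantization all act
on the coarse dynamics too).

Numerical details worth knowing: the reset is applied at the step *after*
the threshold crossing and occupies exactly one fine step (the ISI oracle
accounts for it); the reset path is detached from gradient flow by default
(`detach_reset = FALSE` enables the extra term); ties in the max-over-time
readout break toward the earliest step; input events are binned by
`floor(t/Δt)`; degenerate `tau_mem == tau_syn` is handled by the limit form
of the propagator correction.

## Objectives

Classification uses the softmax negative log-likelihood of per-class scores
taken either as the maximum (`max_over_time_nll`, latency-coded vision
tasks) or the sum (`sum_over_time_nll`, speech-like tasks) of the output
traces over time. Three regularizers shape the solution, all batch-averaged:

* amplitude, $\rho_a \cdot \mathrm{mean}_i (\max_t V_i^O[t])^2$ — keeps
  analog output excursions in range ($\rho_a = 0.01$ by default);
* sparsity, $\rho_b \tfrac{1}{N_H}\sum_i (\sum_t S_i[t])^2$ — quadratic in
  per-neuron spike counts, it can only *reduce* activity because its
  gradient reaches the weights exclusively through the surrogate route (the
  tests assert that a disabled surrogate derivative zeroes it);
* homeostatic, $\rho_r \max(0, \sum_{i,t} S_i[t] - \vartheta_r)^2$ —
  one-sided, used on the recurrent task to cap pathological firing.

A subtlety discovered while testing the documented claim that training can
start from a quiescent hidden layer: with identically-zero output traces
the max-over-time readout ties at the first step, whose value depends only
on initial conditions, and the task gradient vanishes. On the emulated (and
real) substrate the intrinsic readout noise breaks this tie, and training
ignites through the surrogate route; with noise forced to zero and
all-subthreshold weights it does not. The default 1% noise is therefore not
merely cosmetic.

## Encoders and data

`latency_encode()` converts intensities $x \in [0,1]$ to single spikes at
$t = \tau_{in} \ln(x / (x - \vartheta_{in}))$ (no spike at or below the
threshold; later than `t_max` dropped). The defaults $\tau_{in} = 20$,
$\vartheta_{in} = 0.2$, `t_max = 60` put the informative spikes in the
first half of the default 100-step window, which is what makes the
latency-probe experiment (accuracy versus decision horizon) reach its
plateau early. `downscale_image()` implements the 28×28 → crop border →
area-average → 16×16 pipeline; `subsample_channels()` implements the
700 → 70 event-channel rule (omit the first seventy 0-based units, keep
every 9th, remap contiguously — contiguous remapping is an assumption);
`scale_time()` divides event times by a factor (2000 maps seconds of audio
onto model time at the hardware acceleration scale); `jitter_channels()`
reassigns each event to `round(N(i, σ))`, clipped at the edges, and is
applied *before* subsampling — a test pins this composition order.

Because no external download is assumed, `make_latency_images()` and
`make_temporal_patterns()` generate class-structured data with the same
statistical shape: smooth random blob prototypes plus pixel noise (with a
pairwise L2 separation margin enforced, so classes are separable by
construction — a linear classifier exceeds 95% on the defaults), and
spatiotemporal anchor-event patterns with timing jitter, channel jitter,
deletions and background spikes. Classes 1 and 2 of the temporal task are
an order-sensitive pair: identical channels and counts with the temporal
order reversed, so any purely rate-based readout is at chance between
them. Defaults (10 classes × 100 samples, 16×16 or 70 channels, T = 100
steps; 6 × 60 for the temporal task) were chosen once to keep every
experiment in the minutes range on one CPU. What the generators do *not*
emulate: digit-like image structure, speaker identity, realistic cochlear
channel correlations, or long-range temporal dependencies beyond the
anchor motifs — so passing tests demonstrate the mechanics of ITL
self-calibration and regularization transfer, not benchmark-level vision
or speech performance.

The `train_test_split(..., disjoint = TRUE)` variant regenerates the held-
out samples under noise parameters inflated by 1.5, emulating the domain
shift of held-out speakers.

## Reference studies

`study_config()` freezes the four headline experiments; the acceptance
script (`scripts/acceptance.R`) and the test suite run them unchanged.

* **Self-calibration** (`run_selfcal_sweep`): ITL training on substrates
  decalibrated by $\sigma_d \in \{0, 0.3, 0.5\}$ — the graph keeps assuming
  ideal parameters — against transfer of software-trained weights onto the
  same substrates. Expected shape: ITL at $\sigma_d = 0.3$ within two
  accuracy points of the calibrated substrate, while the ITL-over-transfer
  gap widens with mismatch. 70-channel latency task, 64 hidden units,
  30 epochs, 3 seeds.
* **Sparsity** (`run_sparsity_sweep`): $\rho_b$ over three decades
  ($10^{-3}$…1, plus 0). Median hidden spike counts decrease monotonically
  by more than a decade while median accuracy stays on a plateau.
* **Robustness** (`run_robustness`): training at dropout 0 and 0.4 (per-
  batch Bernoulli masks on hidden spikes, mirrored on the substrate
  deployment, off at evaluation), then ablating 0–30% of hidden units
  post-training. Dropout-trained networks inflate their test error
  substantially less at 15% ablation.
* **Recurrence** (`run_recurrence_control`): on the order-sensitive
  temporal task, a fully trained recurrent network against a control whose
  recurrent matrix is the trained one with entries shuffled and frozen
  (input/readout weights retrained from scratch). The trained network
  reaches a lower median test error over 5 seeds; at desk scale the margin
  is a few points — much smaller than on a full speech benchmark, because
  a shuffled reservoir plus trained readout already solves most of the
  synthetic task. Several harder memory-bound task variants were tried and
  rejected: at these network and dataset sizes networks memorize sample
  noise before exploiting temporal order, so the modest-margin comparison
  is the honest version of this experiment.

Hyperparameters the source experiments left unspecified are config-driven
with these defaults: Adam at `lr = 1e-3` (the recurrent study uses
`5e-3`), batch 50, surrogate steepness $\beta = 10$, hidden weight scale
max 1.5, dropout 0, homeostatic $\rho_r = 10^{-5}$ with $\vartheta_r =
300$ on the recurrent study. Every run derives all randomness (data,
initialization, mismatch, noise, shuffling, masks) from one master seed,
and re-running a configuration reproduces its metric CSVs byte for byte.

## A small worked example

```{r example, eval = FALSE}
cfg <- default_config()
cfg$task$samples_per_class <- 30L
cfg$training$epochs <- 10L
res <- run_train(cfg, seed = 1)
res$test_accuracy
tail(res$history, 3)
```

## Known limitations

* The substrate models mismatch, additive Gaussian noise, weight
  quantization and sampled readout — not ADC transfer functions, event-
  router bandwidth, refractory clamping subtleties (a refractory period is
  available but defaults to zero), adaptation currents, or energy/latency.
* BPTT is exact reverse-mode through the full unrolled window (linear in T
  in time and memory); no online or eligibility-trace approximations.
* The acceptance comparisons are relative, scaled-down reproductions of
  effect *shapes* (self-calibration, sparsity plateau, dropout robustness,
  recurrence benefit), not of benchmark accuracies, which require the
  external datasets and, for the hardware numbers, the physical chip.
* At desk scale the sweep medians carry real seed-to-seed variance: the
  difficulty of a generated dataset varies with its seed (prototype
  geometry interacts with the latency encoder's intensity threshold), so
  while the effect *directions* are stable, the margin of a given
  comparison — e.g. how close ITL accuracy at $\sigma_d = 0.3$ sits to the
  calibrated substrate, or how many decades the sparsity plateau spans —
  can move by several points between master seeds. The reference studies
  fix their seeds for exactly this reason; `scripts/acceptance.R --seed`
  reproduces the sweeps under any other seed for inspection.
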