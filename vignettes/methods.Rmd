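---
title: "Spiking-network myoelectric gesture recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking-network myoelectric gesture recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spikeEMG implements a complete surface-EMG (sEMG) gesture-recognition
pipeline built around a spiking neural network (SNN): synthetic HD/LD sEMG
generation, preprocessing, temporal-contrast spike encoding, a
voltage-current leaky integrate-and-fire (LIF) classifier trained by
surrogate-gradient backpropagation through time, three conventional
comparators (LDA, LSTM, CNN), an operation-count inference-power model, and
the cross-validation protocols that tie them together. This vignette is the
package's own account of the models, the parameters that matter, and the
design choices that were genuinely open.

## The synthetic sEMG generator

Real high-density sEMG databases of this kind are rarely deposited, so the
package ships a generator whose output has the statistical structure the
pipeline relies on. Each recording is one 5-second gesture repetition on
either a 128-channel high-density montage (two 6 x 8 arrays at 14 mm
spacing over the forearm extensor and flexor muscles, two 4 x 4 arrays at
18 mm over biceps/triceps) or the 8-channel low-density subset obtained by
`selectLdChannels()` (the centre electrode of each 3 x 3 block of a centred
6 x 6 sub-grid, four per 48-channel array).

Per channel the signal is

> (activation gain x gesture envelope) x modulated band-limited noise
> + measurement noise,

with a 2 s linear onset ramp, a 2 s steady plateau and a 1 s decay. The
activation gain comes from a per-gesture spatial map: a Gaussian blob
(sigma = 1.5 electrode pitches) centred at a gesture-specific lattice
position, jittered per subject. Electrode shift is an integer translation
of those maps on the grids with edge replication, drawn once per trial
(each trial emulates one re-wearing of the device); no rotation is
modelled, matching how such devices are re-worn in practice.

**Why the noise is amplitude-modulated.** A naive model would use plain
band-limited Gaussian noise. That model is degenerate for this pipeline:
the absolute successive difference of *any* Gaussian process has a
half-normal marginal, so an encoder that thresholds |diff| at
mean + theta x sd fires at a shape-determined constant rate on every
channel, and the spatial activation pattern — the class signal — is erased
before the classifier sees it. Real interference sEMG is not Gaussian:
grouped motor-unit firings make it bursty and heavy-tailed (excess
kurtosis well above 3 at moderate contraction). The generator therefore
modulates the band-limited carrier with a log-normal envelope
(`exp(1.3 z)`, z a standardised ~20 ms moving average of white noise),
giving marginals with kurtosis ~15-30 on active channels while the noise
floor stays Gaussian. Under adaptive encoding the spike rate then falls
smoothly from ~0.24 (pure noise floor) to ~0.15 (fully active channel) —
a gain-invariant signature of activation that the network can classify.

What the generator does **not** emulate: motor-unit action-potential
shapes, force levels, fatigue and within-session nonstationarity,
amplifier saturation, power-line interference, or cross-channel
correlation beyond the shared activation maps. Passing tests on this data
therefore demonstrates that the pipeline's machinery works and that its
invariances hold, not that the accuracies of any real-data study
are reproduced.

Seeds are hierarchical (master -> subject -> trial -> repetition), so any
sub-collection regenerates bit-identically in isolation.

## Preprocessing

The pipeline order is fixed: segmentation, resampling, filtering,
normalisation, then windowing.

* **Channel repair** (off by default; the generator produces no broken
  channels): channels whose RMS exceeds 5x the median channel RMS are
  replaced by the mean of their grid-adjacent channels, refusing to repair
  more than 5% of channels.
* **Active-segment extraction**: the across-channel mean rectified signal
  is smoothed with a 200 ms moving average; the segment runs from where
  this envelope first reaches 10% of its peak to where it last does. The
  raw oscillating signal has no meaningful 10% crossing; only an envelope
  does, which is why the smoother exists and why its length is
  configurable.
* **Resampling** to exactly 5,000 points by linear interpolation —
  deterministic, shape-preserving and testable in closed form.
* **Filtering**: 50th-order (51-tap) Hamming windowed-sinc FIR band-pass,
  20-500 Hz. At 1 kHz sampling the upper edge sits at Nyquist, so the
  design degenerates to a high-pass; the residual DC gain of a 51-tap
  window at a 20 Hz edge is nulled exactly by subtracting the tap mean.
  The filter is applied causally with zero initial state and the startup
  transient is retained, for determinism.
* **Min-Max normalisation** to [0, 1], by default per channel (each
  channel's own extrema). A joint mode (one affine map for the whole
  segment) is available; notably, the adaptive spike encoding below is
  *identical* under either mode, because it is invariant to per-channel
  positive rescaling — the choice only affects the fixed-threshold
  encoder and the dense baselines.
* **Windowing**: 100 ms windows at 50 ms increment over the stabilisation
  phase (seconds 2-4), i.e. 39 windows per repetition; at the default
  eight repetitions, nine gestures and five trials this yields 14,040
  samples per participant.
* **Features** (for LDA): per channel MAV, VAR, WL and ZC. MAV and ZC are
  computed on the mean-subtracted window: after Min-Max normalisation the
  literal signal never crosses zero, which would make ZC identically zero;
  mean-centring restores the standard definitions.

## Temporal-contrast spike encoding

A window `s(t)` is encoded by thresholding its successive differences:
`diff(t) = s(t+1) - s(t)`, and `o(t+1) = 1` iff `|diff(t)| >= V_thr1`,
with `o(1) = 0` so the spike window keeps the length T = 100. The
threshold is either fixed (default 0.18) or adaptive,

> V_thr1 = mean(d) + theta x sd(d),   theta = 0.6 by default,

computed per channel from that window's own differences. Two open points
were settled as follows:

* **d = |diff|, not signed diff** (default). On oscillatory EMG the signed
  mean is ~0 and its sd large, so the swept negative theta values would
  produce negative thresholds and a saturated encoder; statistics of the
  absolute differences keep the whole theta sweep meaningful. The signed
  mode is available for comparison.
* **Per-channel thresholds** (default), with a pooled mode available.
  Per-channel granularity is what makes the encoding exactly invariant to
  channel-wise gain changes (electrode impedance, contact quality), which
  is the robustness the method claims; the tests assert bit-identical
  output under amplitudes scaled by 0.01-100x.
* Population (ddof = 0) standard deviation, the convention of the
  temporal-contrast literature; configurable.

The spike release rate SRR = n/(T x N) summarises sparsity; it is
non-increasing in theta and in the fixed threshold, which the sweep tests
assert on generated data.

## The LIF-V-I neuron and the network

Each neuron carries two leaky states, updated in the order current ->
voltage -> threshold test -> reset:

> I(t) = mu I(t-1) + sum_j w_ij S_j(t) + b_i,  mu = exp(-1/tau_syn)
> U(t) = tau U(t-1) + R I(t),                  tau = exp(-1/tau_mem)

with tau_syn = 5, tau_mem = 10, R = 1. A spike fires when U >= V_thr2
(equality fires), and firing neurons reset multiplicatively:
U <- U (1 - p) with p = 1.5, leaving a *negative* voltage that suppresses
immediate re-firing. The LIF-V ablation variant drops the current dynamics
(mu = 0) and uses V_thr2 = 0.5 instead of 10. Biases are included — one
per neuron, inside the current update — which is what makes the
trainable-parameter counts i x h + h x o + h + o.

The network is input -> hidden LIF layer (100 neurons for HD, 20 for LD)
-> second LIF layer with one neuron per gesture. The readout is
softmax((1/T) sum_t U2(t)) over the integration window T = 100. Two
readout ambiguities were settled as: the second layer *does* spike and
reset during readout (a no-reset integrator mode exists for comparison),
and the averaged voltages are the post-reset values. Initial state is
U = I = 0 for every sample, the only choice that makes classification
order-independent. Weights start uniform in (-1, 1)/sqrt(fan-in) under a
fixed seed.

## Surrogate-gradient training

Training is plain SGD (lr 0.1, mini-batches of 1/8 of the training set,
cross-entropy) with backpropagation through time. The hard threshold has
no useful derivative, so the backward pass substitutes the normalised fast
sigmoid

> g(v) = (beta/4) / (1 + beta |v| / 2)^2,   beta = 10,

at membrane distance v = U - V_thr2: even, maximal (beta/4) at the
threshold, unit integral. Two stability choices matter and are deliberate:

* **The reset path is detached from the gradient.** The reset multiplies
  U by (1 - p S); differentiating S there injects a term proportional to
  p x U x g(v), up to ~37 at the threshold, and compounding it over 100
  steps makes gradient norms explode (observed: ~1e5 against ~2 for the
  readout weights, and divergence at every learning rate). Keeping only
  the (1 - p S) factor makes the backward recurrence contractive; this is
  also the default in the established surrogate-gradient implementations.
  The surrogate is applied solely where spikes feed forward between
  layers.
* **Per-tensor gradient-norm clipping (default 0.3).** The
  average-voltage readout amplifies a unit weight perturbation by roughly
  1/((1-mu)(1-tau)) ~ 58, so unclipped SGD at the default lr 0.1
  overshoots; clipping keeps that learning rate stable without changing
  the optimiser. Set `clipNorm = Inf` to disable.

Epochs default to 100 with early stopping on a training-loss plateau
(patience 10, improvement threshold 1e-4); an epoch count is otherwise
arbitrary. Training is bit-reproducible under the config seed.

## Baselines

* **LDA** on the 4 x channels feature vectors, fitted by the closed-form
  Gaussian discriminant with a pooled within-class covariance. A diagonal
  shrinkage of 1e-4 x trace/p is always added: with 512 features and tens
  of training samples the pooled covariance is otherwise singular. The
  implementation is cross-checked against MASS::lda in the tests.
* **LSTM**: one standard 4-gate LSTM layer (hidden size matching the SNN)
  reading the window as T = 100 channel vectors, final-hidden-state
  readout through a dense layer; Adam, lr 0.01. Implemented directly in R
  (no deep-learning framework is required by the package) and verified
  against finite-difference gradients.
* **CNN**: the window is reshaped to a C x H x W image with C = 100 time
  steps as channels and the electrodes row-major on a 16 x 8 (HD) or
  4 x 2 (LD) grid; two blocks of [2 x 2 conv, stride 2, same padding ->
  batch norm -> 2 x 2 max pool] with 32 and 16 filters, then a dense
  softmax layer; Adam, lr 0.01. The pooling geometry is a free choice in
  this architecture family, so: pool 2 x 2 stride 2, skipping any axis of
  extent 1, and the dense layer's input is the realised flatten size.
  Batch norm uses batch statistics in training and exponentially averaged
  running statistics at prediction; on very small sample counts this
  makes tiny mini-batches noisy, so toy-scale fits use larger batch
  fractions. Also finite-difference verified.

## The inference-power model

Costs are counted in relative energy units: an accumulate (AC) 0.1, a
multiply-accumulate (MAC) 3.1. Encoding costs (T x 0.1 + 3.1) ACs/MACs per
channel for the mean and (T x 0.1 + (T+1) x 3.1) for the standard
deviation. Spiking layers cost T x (SRR x fan-in x fan-out x 0.1 +
2 x fan-out x 3.1) — synaptic accumulates gated by the measured spike
release rate plus two state-update MACs per neuron per step. The LSTM and
CNN formulas are dense MAC counts. These formulas are implemented
verbatim, idealisations included: the CNN dense term uses H x W x C2 x o
whatever the realised flatten size, and the LSTM dense term scales with T.
The model is an operation-count idealisation for comparing architectures,
not a profile of this R implementation, and the protocols substitute the
SRRs *measured on the test split* when reporting SNN power.

## Evaluation protocols

All splits partition at repetition, trial or subject granularity — never
at window granularity — so windows from one repetition can never straddle
train and test. `splitByRatio(N)` trains on the first N repetitions in
recording order; leave-one-trial-out (per subject) is the electrode-shift
protocol, since each synthetic trial carries its own shift;
leave-one-subject-out is the user-independent protocol. `runProtocol()`
also drives the theta and V_thr2 sweeps over the standard grids and the
four-scheme ablation {adaptive, fixed} x {LIF-V-I, LIF-V}, recording per
fold the accuracy, the measured SRRs and the power estimate. A plain
one-way ANOVA utility (`oneWayAnova()`) summarises accuracy differences;
degenerate inputs are defined by continuity (no between-group variance:
F = 0, p = 1).

## Problem sizes used by the tests and the acceptance script

The full default dataset (8 subjects x 5 trials x 9 gestures x 8
repetitions of 128-channel 5 s signal) is deliberately never materialised
in the automated runs; the package's claims are checked on scaled
instances, chosen once:

* learning checks: 1 subject, 1 trial, 9 gestures, 2 repetitions, HD
  montage; repetition 1 trains (N = 1 regime), repetition 2 tests; 60
  epochs.
* the encoder/neuron scheme comparison under electrode shift: HD montage,
  2 trials with independent shifts, 2 repetitions, every third window, 50
  epochs, 5 dataset seeds x 2 run seeds.
* sweep monotonicity: the tiny LD dataset (9 gestures x 2 repetitions).

On these sizes the whole pipeline is exercised end to end; the absolute
accuracies depend on the generator's difficulty and are reported as
computed, not tuned to any external figure.

## Known limitations

* The generator's realism is deliberately minimal (see above); directional
  comparisons between encoders/neuron variants on synthetic data are
  sensitive to what the generator does and does not model, and are
  reported as measured.
* The LIF-V-I network with V_thr2 = 10 underfits harder tasks when the
  epoch budget is small; comparisons at desk scale are therefore run at
  matched epoch budgets for all schemes.
* Inference latency is hardware-dependent and out of scope; only
  operation-count power is modelled.
* LD parameter counts follow the true 8-channel input size
  (8 x h + h x 9 + h + 9), not any table that assumes 128 inputs for the
  LD rows.
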