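---
title: "Forecasting wearable motion signals with recurrence plots and a Fourier neural operator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting wearable motion signals with recurrence plots and a Fourier neural operator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rpfno)
```

## The problem

A smartphone strapped to the thigh records 3-axis angular velocity at a
nominal 30 Hz while its wearer walks or runs. Given one second of such a
recording, we want the next ~0.6 s: a short-horizon forecast of the raw
gyroscope signal. Forecasts of this kind support *personalized* movement
models — a model trained on one wearer's gait that recognises and
anticipates that wearer specifically — and, because a forecast is
available before the corresponding observation, they allow an anomaly
detector to warn about an imminent fall slightly earlier than a detector
that only sees observed data.

`rpfno` implements the full pipeline: recurrence-plot encoding of the
sensor stream, a Fourier neural operator (FNO) forecaster, an LSTM
decoder back to raw signals, a matched convolutional baseline, the
per-subject training and cross-subject evaluation battery, and an
energy-score fall early-warning scheme. Because the kind of thigh-gyro
recordings the method targets are not publicly deposited, the package
also ships a synthetic gait generator; every claim the test suite makes
is made on generated data, and the limitations of that are discussed at
the end.

## Recurrence-plot encoding

At each sample index $t$ the three axes are windowed and concatenated
(window size $T_w = 5$, stride 1):

$$X_t = [\omega^x_{t-4..t};\ \omega^y_{t-4..t};\ \omega^z_{t-4..t}] \in \mathbb{R}^{15}.$$

One linear midpoint is inserted between consecutive entries of the whole
concatenated vector (crossing axis boundaries), giving a 29-vector, and
the frame is the *distance-only* recurrence plot

$$Y_t[i,j] = \lVert x_i - x_j \rVert_2,$$

a symmetric, zero-diagonal, nonnegative $29 \times 29$ image. The
classical recurrence plot applies a threshold $\epsilon$ and step
function $\Theta$ to this matrix; both are deliberately dropped here
because binarisation discards amplitude information the forecaster needs.
Two properties of the encoding matter downstream:

* it is invariant to a global sign flip and constant offset of the
  window ($x \mapsto -x + c$), so the decoder can only recover the signal
  up to what its training distribution disambiguates;
* every entry is a distance of *relative* differences, which also makes
  the representation insensitive to slow additive drift of the gyro.

For two-sensor fusion the package builds *cross* recurrence plots,
$Y_t[i,j] = \lVert x_i - y_j \rVert$, pairing the interpolated gyroscope
window (rows) with the accelerometer window ending at the same sample
(columns); these are generally asymmetric with nonzero diagonal.

A forecasting sample pairs $T = 30$ consecutive input frames (1 s at
30 Hz, stride 1) with the next $\hat T = 20$ target frames (~0.6 s) and
the raw 3-axis samples aligned to the target frames' end indices.

Frames are min–max normalised by the training split's global maximum
before entering any model. The models use sigmoid activations, which are
scale-sensitive; leaving raw distances (several rad/s) on the input
would saturate them. The normaliser is stored with the trained model, so
a checkpoint fully determines inference.

## The Fourier neural operator

The forecaster treats the $T$ input frames as $T$ channels per grid
point. A pointwise linear *lift* maps them to `width` channels; $N = 4$
Fourier layers follow; a pointwise linear projection maps to the
$\hat T$ output frames. Each Fourier layer computes

$$v_{n+1} = \sigma\big(\mathcal{F}^{-1}(R_\phi \cdot \mathcal{F}(v_n)) + W_\theta v_n + b\big),$$

where $\mathcal{F}$ is the 2-D discrete Fourier transform over the grid,
$R_\phi$ a complex weight tensor that mixes channels on a truncated set
of low-frequency modes (all other modes are zeroed), $W_\theta$ a
pointwise linear branch, and $\sigma$ the sigmoid. All intermediate
states therefore lie in $(0,1)$; only the projection output is
unbounded.

**Mode truncation.** With `modes = k` the retained block is every mode
with $|p| < k$ and $|q| < k$ along the two grid axes — $(2k-1)^2$
complex weights per channel pair. Because the weights are indexed by
*frequency*, not by grid position, the parameter count is independent of
the grid size $M$, and a trained model can be evaluated at a different
resolution by simply running the same weights on the new grid's
transform (`evaluate_at_resolution()`). The default $k = 8$ keeps every
grid in the resolution-transfer experiment ($M' \in \{17, 23, 29\}$)
admissible, since $2k - 1 \le M'$ is required.

**Implementation.** Since every mode outside the retained block is
zeroed anyway, the package computes the truncated transform directly as
multiplication by the DFT matrix restricted to the retained frequencies
($E\,v\,E^\top$ with $E \in \mathbb{C}^{(2k-1)\times M}$); this is
algebraically identical to an FFT followed by truncation (asserted
against `stats::fft` in the test suite) and considerably faster at
recurrence-plot sizes. The training step — forward pass, MSE loss and
the full analytic backward pass — runs fused in compiled code; every
gradient is verified against central finite differences, and the fused
step is asserted to agree with a plain R reference pass to
$10^{-10}$.

**Initialisation.** Lifting, projection and the pointwise branch use
uniform fan-in scaling; $R_\phi$ is uniform with scale
$1/(\text{width}_{in}\,\text{width}_{out})$, following common
neural-operator practice. `width = 32` is the full-scale default;
desk-scale runs (below) use `width = 8`.

## The convolutional baseline

The baseline replaces the spectral layers with four same-padded
convolutions (kernel 5, stride 1, ReLU after every layer except the
final one) and the projection with three fully-connected layers mapping
the flattened feature map to the $\hat T \times M \times M$ forecast.
The dense head dimensions are tied to $M$, so the baseline cannot run at
an unseen resolution — the structural counterpoint to the operator's
mesh invariance. `n_params()` reports both models' parameter budgets so
comparisons are made at roughly matched capacity.

## The signal decoder

An LSTM consumes the frame sequence (each frame flattened to its $M^2$
entries as one step's input; hidden size 128 by default) and a two-layer
head (hidden → 64 → 3) maps each step's hidden state to the 3-axis
sample at that frame's end index: $\hat T$ frames in, $3 \times \hat T$
samples out. Training pairs are *true* frames and *true* signals; at
inference the decoder receives forecast frames. Signals are standardised
per axis with training statistics (stored in the model and undone on
output). Because of the sign/offset ambiguity of distance images noted
above, decoder quality is scored by per-axis *correlation* on held-out
windows of the same subject; absolute-error claims are confined to the
training distribution. Overlapping decoded segments are stitched
first-wins (the earliest-issued segment keeps each duplicated index),
and uncovered indices are returned as `NA` rather than silently filled.

## Training protocol and evaluation

The full-scale protocol is Adam, batch 32, 200 epochs, MSE loss,
learning rate 0.001 halved every 50 epochs, and a chronological 6:2:2
train/validation/test split (floor-allocated, remainder to train; 3600
samples give 2160/720/720). The split is chronological rather than
shuffled because stride-1 sliding windows make shuffled splits leak
near-duplicate frames across partitions; additionally, validation and
test samples whose frame span crosses a partition boundary are dropped
(the counts are reported by `split_dataset()`). Validation is used only
for curve monitoring, never for early stopping.

**Personalization.** One model is trained per subject. The evaluation
matrix has entry $(i, j)$ = MSE of subject $i$'s model on subject $j$'s
held-out test samples. Normalisation is treated as part of each
*recording's* preprocessing: subject $j$'s frames are always divided by
subject $j$'s stored training maximum, whichever model consumes them.
The alternative — normalising foreign data by the consuming model's own
scale — conflates amplitude differences between subjects with
forecasting mismatch: a model whose subject moves vigorously would see
other subjects' frames shrunk toward zero and score spuriously small
errors on them. A personalized model shows a small diagonal and larger
off-diagonal entries in every row.

**Desk scale.** The package's experiments (test suite and examples) run
at a documented desk scale chosen to keep the full battery at roughly
twenty minutes of single-threaded CPU: six synthetic subjects, 20 s
streams at 30 Hz (547 forecasting samples each), `width = 8`, $k = 8$,
training on every second window of the chronological training block
(165 windows), batch 32, 150 epochs. At these short runs the learning
rate is held constant at 0.001 — the halving cadence of the full-scale
protocol decays the rate long before convergence when the run is a
fraction of the protocol's 200 epochs, and the desk-scale models are
deliberately trained to the point where per-subject specialisation is
established. The decoder trains for 40 epochs (hidden 64, head 32); the
pooled walking+running forecaster behind the fall detector for 60; the
operator-vs-convolution comparison uses a deliberately small matched
budget (identical training windows and 6 epochs for both models) and is
reported as a logged regression observation rather than asserted: at
such budgets the baseline's dense head, which can memorise the mean
frame in a handful of steps, frequently attains the lower MSE, and the
relative ordering of the two architectures at a full 200-epoch budget is
not resolved by the desk-scale runs.

## Fall early warning

A two-layer classifier (one hidden layer, two logits) is trained by
softmax cross-entropy to distinguish the normal motions — walking vs
running — from *forecast* frame stacks, flattened. The
out-of-distribution statistic is the energy score

$$E(z) = -\log \sum_i e^{z_i},$$

computed from the logits with an overflow-safe log-sum-exp: familiar
motion produces a confident logit and low energy; motion unlike either
class produces high energy. The threshold $\tau$ is the 0.95 empirical
quantile (linear-interpolation convention) of energies on *normal
training windows only* — falls are never used for calibration, so the
scheme is one-class: by construction about 5% of in-distribution windows
exceed $\tau$.

At detection time two energies are computed at each anchor, both from
data available at that moment: the energy of the classifier on the
forecast next-$\hat T$ frames, and on the $\hat T$ most recently
*observed* frames. An anchor whose forecast energy exceeds $\tau$ raises
a `potential_fall` alert; the event is *confirmed* when actual fall data
arrives after the risk signal — at the first anchor strictly after the
first alert whose observed energy also exceeds $\tau$ — and `alert_lead`
is the gap in samples. The package asserts only this ordering — the
warning precedes the observed-data confirmation on injected falls — and
makes no clinical sensitivity claim: the synthetic fall template has no
pre-impact precursor, so no detector, forecast-based or not, could fire
before the physical onset itself.

The classifier's hidden layer is a sigmoid rather than a ReLU by
design: with an unbounded piecewise-linear hidden layer, logits grow
linearly with the input scale, so a high-amplitude out-of-distribution
window (an impact burst is several times the largest training distance)
can land an arbitrarily *confident* logit and score a deceptively low
energy. The bounded hidden layer saturates far outside the training
range, capping the confidence any unfamiliar input can earn, which
restores the intended behaviour of the energy statistic.

## The synthetic gait generator

Each synthetic subject is a per-axis harmonic model: 2–3 harmonics of a
subject-specific stride frequency (walking 1.4–2.0 Hz, running
2.4–3.0 Hz; cohorts enforce pairwise gaps of at least 0.05 Hz), base
amplitudes drawn in 0.5–3 rad/s and decaying with harmonic order,
axis-specific phases, plus i.i.d. Gaussian noise (default sd
0.05 rad/s). Accelerometer streams reuse the harmonic model with shifted
phases and a gravity-like constant on the z axis. Repeated *recordings*
of one subject share the waveform and differ in the noise draw. A fall
is a burst-then-rest template: ~0.5 s of broadband motion with peak
amplitude 3.5× the pre-onset per-axis maximum (impact), then near-zero
signal to the end of the recording (lying still). All generation is
bit-reproducible under the subject's seed.

What the generator does **not** emulate: soft-tissue and clothing
artefacts, turning, stopping and other non-steady gait, inter-stride
variability beyond white noise, realistic fall kinematics (pre-impact
flailing, multi-phase impacts), and the waveform idiosyncrasy of real
humans, which is far richer than a harmonic stack. Passing tests
therefore demonstrate that the pipeline's machinery behaves as designed
— encode/forecast/decode round trips, resolution transfer, per-subject
specialisation, energy separation of a gross out-of-distribution event —
not that the method achieves any particular accuracy on real wearables.

## Numerical choices and degenerate inputs

* Resampling uses a half-open uniform grid: `floor(duration × rate)`
  samples with duration defined as $N/\text{rate}$, so 60 s at 30 Hz is
  exactly 1800 samples and resampling a uniform stream to its own rate
  is the identity. Edge extrapolation is constant.
* Guard trimming removes `round(seconds × rate)` samples per end and
  re-zeroes timestamps.
* The empirical quantile for $\tau$ is type 7 (R's default linear
  interpolation), so energies $\{1..100\}$ at 0.95 give 95.05.
* `resize_frames()` is separable bilinear interpolation
  ($P A P^\top$), exact on bilinear ramps.
* Constant windows produce all-zero recurrence plots; a zero training
  maximum falls back to a unit normaliser.
* Training aborts with a diagnostic on non-finite loss rather than
  continuing from a poisoned state.
* With a fixed seed (and single-threaded BLAS) profile generation,
  training and inference are bit-reproducible; batch order is drawn from
  the training seed.

## Known limitations

* The decoder recovers signals up to the information a distance image
  retains; subjects whose training data do not break the sign/offset
  symmetry decode to plausible but possibly reflected waveforms.
* The energy detector is calibrated on two normal classes only; its
  behaviour on unmodelled *normal* activities (stairs, sitting down) is
  untested here and the false-alarm rate outside walking/running is
  unknown.
* Mesh invariance is architectural, and the resolution-transfer
  comparison has a floor set by the data, not the operator: a
  $T_w' = 3$ window encodes genuinely different pairwise distances than
  a bilinearly downsampled $T_w = 5$ window. On the desk-scale
  experiment the relative Frobenius mismatch between the two encodings'
  *target* frames is about 0.38 at $17 \times 17$ (0.20 at
  $23 \times 23$), so even a perfect forecaster's two routes would
  disagree by that much at the smallest grid; the trained operator's
  prediction mismatch (≈0.26 at 17, ≈0.13 at 23) sits below the data
  floor only because its predictions are smoother than the targets.
* Desk-scale models are small; full-scale defaults (`width = 32`,
  200 epochs) were not run inside the package's own test budget.
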