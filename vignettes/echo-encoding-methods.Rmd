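---
title: "Methods: compressive encoding of FM sonar echoes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compressive encoding of FM sonar echoes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modeling choices, numerical methods and default
problem sizes used throughout `sonocode`. The package asks a single question
end to end: how much of the spectrotemporal information in an FM sonar echo
survives compression into a small fixed-length code, and which perceptual
tasks that code can and cannot support once a physiologically calibrated
internal noise is added.

## 1. Signal model

**Emission.** The default call is a 1 ms hyperbolic (linear-period) sweep
from 70 kHz down to 30 kHz at `fs = 360` kHz, unit peak amplitude
(`make_emission()`). A hyperbolic sweep has the property that the
instantaneous period grows linearly in time, which makes per-channel
dechirping (below) an exact time shift rather than an approximation.

**Targets.** A target is an impulse response: a sparse set of glint delays
and linear amplitudes (`impulse_response()`, `two_glint_ir()`,
`random_ir()`). Echo synthesis is exact delay-and-sum convolution of the
emission with this impulse response, evaluated in the frequency domain so
that glint delays are *not* quantized to the sample grid
(`synthesize_echo()`). Fractional delays matter here: the discrimination
experiments probe delay offsets of a few microseconds, i.e. a fraction of
the 2.78 µs sample period.

Two glints separated by a lag $\tau$ interfere, and the echo magnitude
spectrum carries notches at odd multiples of $1/(2\tau)$
(`notch_frequencies()`, `tau_for_notch()`). This is the physical carrier of
fine delay information at the microsecond scale: the delay cue becomes a
spectral-interference cue.

**Size scaling.** `scale_ir()` rescales a target by a geometric factor $s$:
glint lags stretch by $s$ about the leading glint and amplitudes scale by
$s^2$ (reflecting area). This is the stimulus transformation behind the
scale-invariance experiment.

**Analysis window.** All echoes live in a fixed 7000-sample (19.44 ms)
window. The window is a package design choice: it holds a full echo train
from targets up to a few meters away at the default ranges while keeping the
cochleogram (20 × 7000 = 140 000 samples) small enough that ensemble
covariance work fits comfortably in memory on a single core.

## 2. Cochlear front end

`cochleagram()` applies, in order:

1. a 20-channel gammatone FIR filterbank (order 4, 1024 taps, each filter
   normalized to unit peak magnitude response), with center frequencies
   spaced uniformly on the ERB-rate scale between 16 and 70 kHz;
2. half-wave rectification;
3. power-law compression with exponent $\gamma = 0.4$;
4. a causal 2nd-order Butterworth low-pass at 1 kHz (envelope smoothing),
   clamped at zero.

Every stage is homogeneous: scaling the input waveform by $g$ scales the
cochleogram by exactly $g^\gamma$. The package leans on this law in two
places: `scale_cochleogram()` applies level roves without recomputing the
front end, and `normalize_reference_level()` solves for the waveform gain
that puts an ensemble's cochleogram ceiling at a chosen value in model units
(the exponent makes the inverse closed-form). The law is asserted to
numerical precision in the test suite.

**Dechirping.** `dechirp()` advances each channel by the (integer-sample)
time at which the emission sweep passes through that channel's center
frequency. After dechirping, a single-glint echo produces near-simultaneous
peaks across channels, so glint structure appears as vertical ridges. The
per-channel shifts are integer because they compensate a channel-dependent
*group* delay of order milliseconds; sub-sample precision is only needed for
the *stimulus* delays, which are handled in synthesis.

## 3. Compressive encoder

`fit_basis()` computes a PCA of the ensemble of flattened cochleograms
followed by a symmetric FastICA rotation (log-cosh nonlinearity, tolerance
1e-4) of the whitened scores. PCA on 140 000-dimensional vectors is done
via the Gram matrix ($n \times n$, with $n$ the number of cochleograms)
rather than the covariance matrix, so cost scales with the ensemble size,
not the signal dimension. Both steps are seeded and deterministic.

`encode()` maps a cochleogram to the 25-dimensional code
$c = W\,\mathrm{diag}(1/\sigma)\,V^\top(x - \mu)$; `decode()` inverts the
(orthonormal) ICA rotation and returns the rank-25 PCA reconstruction — the
test suite pins `decode(encode(x))` to an independent SVD oracle. The
choice of 25 components is a tuned, asserted property of the generator: the
default synthetic ensemble is constructed so that 25 components retain at
least 99 % of its variance (see Section 6).

`component_field()`, `best_delay()` and `response_width()` reshape ICA
components back into 20 × 7000 fields and summarize where along the
dechirped time axis each component concentrates its energy.

## 4. Internal noise and its calibration

The noise model is i.i.d. additive Gaussian noise on every cochleogram
sample (`noise_model()`). For an observer that discriminates two stimuli by
the *summed* cochleogram statistic $\Sigma C$ over all $K = 140\,000$
samples, the proportion correct has the closed form
$\Phi\!\left(\Delta / (\sigma\sqrt{2K})\right)$ where $\Delta$ is the
difference of the summed noiseless cochleograms. `discrimination_probability()`
evaluates this by exact sampling of the Gaussian sum and matches the closed
form to Monte-Carlo precision.

Calibration proceeds in two steps (`calibrate_reference_gain()`,
`calibrate_internal_noise()`):

1. fix the physical scale: the gain that brings the cochleogram of a
   reference single-glint echo at 11 ms to a ceiling of 15 model units;
2. solve for $\sigma$ such that a 5 dB intensity increment of that
   reference echo is detected on 70 % of trials under the $\Sigma C$
   statistic.

Both steps are deterministic up to the Monte-Carlo seed, and the bisection
in step 2 starts from the analytic solution, so it converges in a few
iterations. At the defaults this yields $\sigma \approx 51.3$ model units.
An important structural fact, proved in the test suite: the calibrated
ratio $\sigma / \Sigma(S_\mathrm{ref})$ — and therefore every downstream
threshold — is invariant to the reference gain, because $\sigma$ co-scales
with $g^\gamma$. The intensity anchor pins the *effective* noise level of
the whole system; no later choice of units can move it. The consequences
for the delay-discrimination experiment are discussed in the package
README under "Reproduction notes".

## 5. Simulated psychophysics

`experiment_config()` defines four two-alternative forced-choice studies;
`run_experiment()` trains a discriminator network on codes and reports a
psychometric curve:

1. **Delay discrimination** — two-glint stimuli, glint-lag offsets of
   5–1000 µs against a reference, 30 dB joint level rove.
2. **Notch detection** — spectral notches on a grid across the band, with
   per-glint roving.
3. **Scale invariance** — targets rescaled geometrically; the default grid
   is 15 scale conditions spanning 0.65–1.5 and containing the trained
   scale 1 exactly. Protocol 1 trains at scale 1 only; protocol 2 trains at
   {0.65, 1, 1.5} and tests interpolation.
4. **Elevation discrimination** — a toy head-related transfer function
   (HRTF) imposes a Gaussian spectral notch (25 dB deep, 2 kHz wide) whose
   center moves at 0.5 kHz per degree around 50 kHz; the task is telling
   elevation $e$ from $-e$. The notch family is validated to stay inside
   the 30–70 kHz emission band across the ±20° grid — a notch outside the
   band is inaudible through the front end, which would silently make
   extreme elevations *harder* instead of easier.

The discriminator is a small hand-rolled multilayer perceptron
(25–50–50–1, ReLU, sigmoid output, RMSProp; `mlp_spec()`/`mlp_train()`),
trained per condition on standardized codes. Stimulus noise is applied in
code space: because the encoder is linear, cochleogram-sample noise
$\mathcal{N}(0, \sigma^2 I)$ maps to code noise with covariance
$\sigma^2 U_m U_m^\top$, which `build_trials()` samples directly via a
Cholesky factor. This makes a 2000-trial psychometric point cost
milliseconds instead of minutes, and the test suite verifies the empirical
code-noise covariance against the analytic form. Per-glint roves and other
non-joint manipulations fall back to a literal cochleogram-space path.

`threshold_from_curve()` interpolates the 75 %-correct crossing walking
from the hardest condition toward the easiest, and labels the result
`interpolated`, `at_edge`, or `beyond_range`. `fold_curve()` folds signed
conditions (e.g. ±elevation) into difficulty magnitudes.

**Place recognition.** `train_place_net()` trains a
25–50–100–50–21 softmax network (Adam, cross-entropy) to name the location
that produced each echo, with a confusion matrix and `confusion_report()`
summaries.

## 6. Synthetic echo ensemble

No field recordings ship with the package; `generate_dataset()` synthesizes
an ensemble designed to *behave* like a sonar survey of distinct places:

- **21 locations** in two regimes: 11 `sparse_glints` scenes (few strong
  reflectors, like man-made structure) and 10 `dense_stochastic` scenes
  (Poisson glint counts around 25, log-normal reflectivities, like
  foliage). Three locations are *siblings* — perturbed copies of another
  location — planted so that place-recognition errors have a place to go.
- **Poses**: each location is observed from multiple poses; a pose jitters
  glint ranges and reflectivities slightly. Per pose, 3 echo repetitions
  with independent measurement noise are averaged (`average_repeats()`),
  which the tests verify cuts noise variance by 3.
- **Propagation**: spherical spreading ($1/r^2$ two-way amplitude) and
  frequency-dependent atmospheric absorption applied per glint.

The default run produces 275 averaged cochleograms (825 echoes) across the
21 locations; `preset = "paper"`-style scaling up to 338 poses / 1014
echoes is available for larger studies. All jitter magnitudes are tuned so
that the top-25 principal components of the default ensemble capture
≥ 99 % of its variance — this is an asserted property of the generator, not
a measured hope, and it is stable across seeds (99.36–99.40 % on seeds 1,
7, 42).

Limitations worth naming: poses jitter glints rather than displacing a
simulated sensor through space, so parallax and aspect-dependent occlusion
are not emulated; the HRTF is a one-cue toy; and reverberation between
glints is ignored (echoes superpose linearly).

## 7. Information-capacity accounting

`capacity_report()` compares three budgets, each an (entropy per sample) ×
(effective number of independent samples) product:

- the full cochleogram: 140 000 samples at the measured marginal entropy,
  discounted by the oversampling factor `oversample_factor(360000, 1000)`
  = 180 implied by the 1 kHz envelope bandwidth at 360 kHz sampling;
- the active region only (`active_mask()` thresholds away silent
  time-frequency cells);
- the 25-dimensional code at its measured per-component entropy.

Entropies are plug-in estimates from equal-width histograms
(`sample_entropy_bits()`), with hand-computable oracle cases in the tests.
At the defaults this reproduces the package's headline arithmetic:
3422 bits (full), 2792 bits (active region), 332 bits (code) — a
compression of roughly an order of magnitude in bits for the tasks the
code supports.

## 8. Reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state. `scripts/acceptance.R` (run against the installed package)
derives all sub-seeds from a single `--seed` argument and writes its
measured targets as JSON. The test suite pins numerics against independent
oracles — FFT interference formulas, SVD reconstructions, closed-form
Gaussian psychometrics, Kolmogorov–Smirnov checks on samplers — rather than
against stored outputs of the package itself.
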