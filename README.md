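# sonocode

Compressive efficient coding of FM bat sonar echoes.

Echolocating FM bats resolve target structure at microsecond delay scales,
yet the auditory nerve transmits orders of magnitude fewer bits than the raw
acoustic waveform carries. `sonocode` models the complete pipeline behind
that observation: a gammatone cochlear front end with dechirping, a
25-component PCA+ICA compressive encoding fitted to an echo ensemble, an
internal-noise model calibrated against the echo-intensity just-noticeable
difference (5 dB detected on 70 % of trials), and downstream evaluations —
simulated two-alternative forced-choice psychophysics (delay, spectral
notch, size scaling, elevation), place recognition over 21 locations, and
Shannon information-capacity accounting. A synthetic echo-ensemble
generator stands in for field recordings, emulating sparse man-made and
dense foliage-like reflectors with spherical spreading and
frequency-dependent atmospheric absorption.

See `vignettes/echo-encoding-methods.Rmd` for the methods in detail.

## Worked example

The output below is the actual printed output of this code (it takes a
couple of minutes; the ensemble and basis steps dominate).

```r
library(sonocode)

## 1. Two glints separated by tau interfere: notches at odd multiples
##    of 1/(2*tau). tau = 10 us -> 50 kHz, 150 kHz, ...
notch_frequencies(10e-6, m_max = 1L)
#> [1]  50000 150000

## 2. Synthesize a two-glint echo of the 1 ms 70->30 kHz sweep and run
##    the cochlear front end (20 gammatone channels, rectify, power-law
##    compression, 1 kHz smoothing), then dechirp.
em <- make_emission()
em
#> <echo_wave> 360 samples @ 360 kHz (1.00 ms), peak 1
echo <- synthesize_echo(two_glint_ir(two_glint_spec(10e-6)), em)
cc <- dechirp(cochleagram(echo))
cc
#> <cochleogram> 20 x 7000 (dechirped), max 0.318 m.u.

## 3. Synthetic ensemble: 21 locations, multiple poses each, 3 echo
##    repetitions averaged per pose.
dataset <- generate_dataset(seed = 1)
dataset
#> <echo_dataset> 825 echoes (275 poses x 3 repeats) at 21 locations
ens <- ensemble_cochleograms(dataset)

## 4. Bring the ensemble onto the calibrated reference level (cochleogram
##    ceiling of 15 model units) and fit the 25-component PCA+ICA basis.
ref_gain <- calibrate_reference_gain()
ref_gain
#> [1] 14969.57
cochs <- lapply(ens$cochs, scale_cochleogram, ref_gain)
basis <- fit_basis(cochs, 25, seed = 11)
basis
#> <encoding_basis> 25 components over 140000-dim observations (n = 275)
#>   top-25 PCA variance: 99.36 %; ICA converged in 19 iterations

## 5. Calibrate the internal noise at the intensity JND: a 5 dB increment
##    of the reference echo detected on 70 % of trials.
noise <- calibrate_internal_noise(ref_gain, seed = 3)
noise
#> <noise_model> sigma = 51.31 m.u.

## 6. Simulated delay-discrimination experiment: a network trained on the
##    25-D codes, glint-lag offsets of 5-1000 us, 30 dB level rove.
res <- run_experiment(experiment_config(1, ref_gain = ref_gain),
                      basis, noise, seed = 2024)
res$curve
#>    condition pct_correct   n
#> 1          5        54.0 200
#> 2         10        51.0 200
#> 3         15        57.0 200
#> 4         20        52.0 200
#> 5         30        55.0 200
#> 6         50        69.5 200
#> 7        100        77.5 200
#> 8        200        89.0 200
#> 9        500        87.5 200
#> 10      1000        88.5 200
res$threshold   # 75 %-correct crossing, us
#> [1] 84.375

## 7. Information-capacity accounting with empirically measured entropies.
capacity_report(cochs, encode(cochs, basis))
#> <capacity_report>
#>   H(S) = 6.93 bits/sample (empirical 6.93), H(C) = 5.19 bits/coeff (empirical 5.19)
#>   samples: 140000 total, 71331 active; oversample x180
#>   I_S = 5392 bits (full), 2747 bits (active); I_C = 130 bits (reduction 95.3 %)
```

`capacity_report()` also accepts fixed per-sample entropies via `h_s` /
`h_c` for back-of-envelope budgets; `capacity_bits(140000, 4.40, 180)`
reproduces the headline 3422-bit figure for a 4.40 bits/sample cochleogram.

## Tests and acceptance script

```sh
Rscript -e 'devtools::test()'
```

The suite pins the numerics against independent oracles (FFT interference
formulas, SVD reconstructions, closed-form Gaussian psychometrics,
distributional tests on samplers). **One test fails by design**: the
acceptance criterion asserting the published ~12 µs delay JND (see
Reproduction notes below).

`scripts/acceptance.R` runs three headline measurements against the
installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

```json
{"t1":{"value":64.4,"n":1},"t6":{"value":99.3593374280358,"n":275},"t7":{"value":79.6875,"n":2000}}
```

- `t1` — first interference notch for a 7.77 µs two-glint lag, in kHz
  (64.4, exact).
- `t6` — percent variance captured by the top-25 principal components of
  the default synthetic ensemble (≥ 99 % is an asserted, tuned property of
  the generator; 99.36–99.40 % across seeds).
- `t7` — Experiment-1 delay JND in µs at the 75 % criterion (see below).

## Reproduction notes

The delay-discrimination threshold measured here is **~80 µs**, not the
~12 µs delay JND reported in the behavioral literature for FM bats. This
is not a training or readout problem; under this package's noise
calibration the two behavioral anchors are mutually inconsistent, which we
can show exactly:

1. **The intensity anchor fixes the effective noise level, with no free
   parameters left.** The internal noise σ is chosen so that a 5 dB
   intensity increment of the reference echo is detected on 70 % of trials
   by the summed-cochleogram statistic ΣC over all K = 140 000 samples.
   That makes the ratio σ/Σ(S_ref) = (10^0.1 − 1)/(√(2K)·Φ⁻¹(0.70)) a
   closed-form constant. Because the front end is homogeneous (a waveform
   gain g scales the cochleogram by g^0.4 exactly), σ co-scales with any
   choice of reference gain — every downstream threshold is invariant to
   the physical units.

2. **An ideal observer of the 25-D code cannot reach 12 µs under that
   noise.** With code-space noise covariance σ²·U_mU_mᵀ, the optimal
   discriminability is d′ = √(Δcᵀ Σ⁻¹ Δc). At the calibrated σ this gives
   d′ ≈ 0.27 at a 12 µs offset and d′ ≈ 0.8 at 36 µs; the 75 % criterion
   (d′ ≈ 0.95 for 2AFC) is crossed only near ~60 µs. The trained-network
   thresholds of ~80 µs sit close to that ideal-observer ceiling, i.e. the
   readout is nearly efficient.

3. **Reaching 12 µs breaks the other anchor.** A σ small enough for a
   12 µs JND (about a factor of 5 below calibration) would make the 5 dB
   intensity increment detectable on ~99.6 % of trials — far from the 70 %
   it is calibrated to. The two published anchors differ by a factor of
   ~25 in implied d′ and cannot hold simultaneously under a single additive
   cochleogram noise source with the ΣC intensity statistic.

4. **Control:** with σ = 0 the same network scores 100 % at every offset
   down to 5 µs, confirming the encoder and discriminator are not the
   bottleneck — the fractional-delay synthesis, cochlear interference cue
   and 25-D code all carry the information.

The acceptance test for this criterion states the published bound
(`threshold < 36 µs`) and fails honestly rather than weakening the
assertion or re-tuning the noise after the fact. Everything needed to
reproduce the analysis is seeded; rerun `scripts/acceptance.R` with any
seed to regenerate `t7` (~10 % trial-to-trial variability, consistently in
the 75–90 µs range).
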