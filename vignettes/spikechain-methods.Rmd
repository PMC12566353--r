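---
title: "Methods: behavioral models, calibration and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral models, calibration and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikechain)
```

This vignette documents the modeling decisions behind `spikechain`: what
each stage model assumes, how the graded distortion levels are defined and
calibrated, what the synthetic benchmark does and does not emulate, and the
numerical conventions used throughout. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The recording chain

A recording channel is modeled as LNA → PGA → ADC, followed by the digital
spike band-pass of the processing pipeline. All stages run sample-synchronously
at a single model rate, 24 kHz by default — a common extracellular recording
rate. Using one rate everywhere matters because the stage non-linearity
depends explicitly on the sampling period (Section 3); a distortion level
calibrated at one rate is only meaningful for signals processed at that rate.

### 1.1 Linear stage dynamics

The LNA is the classic capacitive-feedback topology: input capacitance
`Cin`, feedback capacitance `Cf`, a MOS-bipolar pseudo-resistor `Rf` across
the feedback, and an OTA with transconductance `Gm` driving a load `Cl`.
Under deep feedback the closed loop is

$$H_L(s) = \frac{C_{in}}{C_f}\cdot\frac{-sR_fC_f}{1+sR_fC_f}\cdot
\frac{1}{1+s\,C_L/(G_m\beta)},$$

with the mid-band feedback coefficient $\beta = C_f/(C_{in}+C_p+C_f)$ and
equivalent load $C_L = C_l + (1-\beta)C_f$. The first factor blocks
electrode DC offset (high-pass corner $1/2\pi R_fC_f$, ≈ 80 Hz at the
10 GΩ/200 fF defaults — below the 200 Hz analysis band, which is why 10 GΩ
is the default where no value is otherwise specified); the last factor is
the loop-bandwidth pole. The exact frequency-dependent $\beta(s)$ enters
only through the divider factors; using its mid-band limit in the pole
matches the approximation chain that derives the closed loop (the
feedback-loading term is dropped because $R_f \gg R_o$). The test suite
confirms that closing the loop around the open-loop gain
$H_o(s) = G_mR_o\beta/(1+sR_oC_L)$ reproduces this closed-loop response at
mid-band when the DC loop gain is large.

The PGA is the same structure without the high-pass factor: DC gain
$C_1/C_2$ and a single pole at $G_{m2}\beta_P/2\pi C_{L2}$.

Defaults: LNA gain 100 (Cin = 20 pF, Cf = 200 fF), GBW = 10 MHz into 1 pF
(hence Gm ≈ 62.8 µA/V via GBW = Gm/2πCl); PGA gain 10, GBW = 0.8 MHz.

**Discretization.** Stages filter sampled signals through the bilinear
transform of the continuous closed loop. The bilinear transform preserves
stability and the low-frequency gain/corner placement — the only properties
the analysis uses. At 24 kHz the closed-loop pole of a fast stage
(~80 kHz) lies above Nyquist; it is then frequency-warped, which leaves the
mid-band response untouched but compresses the response near Nyquist. The
stage raises a classed warning (`spikechain_alias_warning`) when this
happens so that callers are aware; the experiment drivers muffle it.

### 1.2 The non-linearity module

An OTA responding to a changing demand passes through a slewing phase
governed by its slew rate SR and a settling phase governed by its bandwidth.
With integration time constant $\tau = 2\pi C_{in}C_l/(G_mC_f)$, demanded
slope $|v|/\tau$ and sampling period $T_s$, the residual error at the
sampling instant falls into three cases:

* **slope > SR and** $t_{sl} \ge T_s/2$: still slewing at the sample —
  $\mathrm{error} = |v| - SR\,t_{sl}$;
* **slope > SR and** $t_{sl} < T_s/2$: slews for $t_{sl}$, settles for
  $t_{lin} = T_s/2 - t_{sl}$ —
  $\mathrm{error} = (|v| - SR\,t_{sl})\,e^{-t_{lin}/\tau}$;
* **slope ≤ SR**: purely linear settling —
  $\mathrm{error} = |v|\,e^{-T_s/2\tau}$;

with $t_{sl} = |v|/SR - \tau$ (clipped at zero) and all errors clamped
non-negative. `slew_error()` exposes exactly this case analysis.

`process_amplifier()` injects the error *feed-forward*: the module sits
after the gain stage, evaluates the three-case error on the instantaneous
magnitude of the ideal stage output, and subtracts it in the direction of
the current signal change, so the output lags the ideal response. Two
design consequences motivated this choice over a recursive (feedback)
tracker:

1. it leaves the fundamental of a test tone essentially untouched, so a
   stage's SNR is independent of its distortion level — the behavior the
   distortion-ladder characterization relies on;
2. the dominant knob becomes $e^{-T_s/2\tau}$, which grows smoothly as GBW
   falls, giving a monotone, unbounded THD range to calibrate against (a
   feedback tracker saturates near −48 dB because its settling pole
   attenuates the fundamental as fast as it creates harmonics).

With SR unset the module is bypassed entirely (distortion level 0): the
stage then equals its linear filter response to machine precision, which
the suite asserts at 10⁻⁹ of full scale.

One known artifact: in the deep case-1 regime the error expression
saturates at $SR\,\tau$, so pushing SR alone to extremely small values
eventually *reduces* the injected error. The monotonicity of THD in SR
therefore holds over the moderate range the calibration uses (verified in
the tests over a 10× range) but not asymptotically.

### 1.3 Noise

Stage noise is a white input-referred source with one-sided PSD floor
`noise_floor` (V²/Hz), realized per sample with variance
`noise_floor · fs/2` and filtered through the stage response. In the spike
band the thermal floor dominates (1/f noise is below the 200 Hz corner of
the analysis band), so a white model is adequate. Default floors are set so
the standard 100 µV tone yields stage SNRs of ≈ 32.4 dB (LNA) and
≈ 33.1 dB (PGA) at the 24 kHz rate — about 15 nV/√Hz input-referred, a
realistic figure for neural front ends.

## 2. The converter

The flash architecture is the behavioral model of choice because its
non-linearity has a direct physical dial: the 2ⁿ−1 ladder thresholds.
Ideal mid-rise thresholds are perturbed by N(0, (σ·LSB)²) and re-sorted —
a bubble-corrected flash encoder behaves monotonically — and the digital
side reconstructs mid-tread with the *ideal* LSB, since the back end does
not know the mismatch. The perturbation is drawn once per ladder (static
resistor mismatch), reproducibly under a seed. INL/DNL follow directly;
the telescoping identity INL_{i+1} − INL_i = DNL_i is exact.

Tone characterization drives the converter at full scale (amplitude
0.999 × half-range): the level-0 reference values (SNR ≈ 74 dB,
ENOB ≈ 12.0 for 12 bits) are only realized at full-scale drive, since every
dB of backoff costs a dB of SNR. For chain simulations the default
reference range (±0.6 V) leaves headroom above the amplified spikes
(≈ ±0.25 V after the 60 dB front end), with a saturation warning if more
than 1 % of samples clip.

## 3. Single-tone characterization

The standard probe is a sine at ≈ 1.11 kHz and 100 µV. Records are
coherent: an integer number of tone cycles, rectangular window. Two
conventions matter at a 24 kHz rate:

* **Prime-cycle coherence.** For a 24 000-sample record, 1110 Hz shares a
  factor 30 with the record length: the sampled tone revisits only 800
  distinct phases, and the quantizer error pattern — periodic with the
  tone — collapses onto harmonic bins, corrupting level-0 THD. The helper
  `coherent_tone_freq()` returns the nearest frequency whose cycle count is
  coprime with the record (1109 Hz here, within 0.1 % of nominal), the
  standard coherent-testing rule.
* **Alias folding.** THD counts 10 harmonics; those above Nyquist fold back
  at known frequencies and are collected there, as in standard converter
  test practice.

Power accounting: fundamental and harmonic bin clusters, DC excluded,
everything else is noise; THD, SNR, SNDR, SFDR and ENOB = (SNDR−1.76)/6.02
follow. Non-coherent records fall back to a 4-term Blackman-Harris window
with 7-bin clusters; the suite checks the two paths agree within 1 dB.
`welch_psd()` (averaged Hann-windowed overlapping segments, Parseval-
normalized) supports noise-floor checks and spectrum plots. Waveform
deformation is scored by NRMSE — RMS error over the reference's
peak-to-peak range, a scale-free choice that compares across clusters of
different amplitude.

## 4. Distortion levels and calibration

A *distortion level* is defined operationally by the THD the stage produces
on the standard tone; level 0 is the linear reference. For the amplifiers,
the two knobs move together — SR/GBW is pinned to a constant ratio
(10⁻⁴ V, the ratio of the nominal LNA design point; the same ratio is used
for the PGA, whose printed ratio is internally inconsistent with the
4πI_ds/G_m identity) — so a single scale factor g multiplies both, and
bisection on log g lands each THD target. Amplifier calibration runs with
the noise floor off: the injected distortion is deterministic and noise
only biases the spectral estimate. For the converter the knob is the
perturbation amplitude σ; THD for a given σ is the median over 10
independent ladder draws, and bisection runs on that median. Achieved
levels within ±1.5 dB of target are flagged `met`; unreachable targets are
reported with the best value found. Ladder-draw THD scatters with a
standard deviation of roughly 2.5 dB at moderate σ, so a 10-draw median
re-measured on fresh seeds wanders by ±1–2 dB around the calibrated value —
an intrinsic property of static-mismatch distortion, not a calibration
error.

## 5. The synthetic benchmark

`generate_recording()` emulates the statistical structure of a curated
annotated extracellular benchmark at the scale of ~4800 annotated events in
14.4 million samples (600 s at 24 kHz, ~8 Hz total rate; the reduced 60 s
preset keeps the same density for repeated sweeps).

* **Templates**: biphasic (negative trough, positive overshoot) difference-
  of-Gaussians shapes, zero net area (AC-coupled), with per-unit widths,
  overshoot delays and fractions stratified across physiological ranges so
  shapes are pairwise distinct. Trough amplitudes default to 150–250 µV:
  every annotated unit then clears the 4σ_N detection threshold with ≥3σ
  margin after band-passing, as annotated (sortable) units in curated
  benchmarks do. Units whose troughs sit at 3–4× the noise scale would lose
  an arbitrary fraction of their spikes at a fixed 4σ threshold, making
  "accuracy" reflect amplitude draw luck rather than chain distortion.
* **Spike trains**: homogeneous Poisson per unit with a 2 ms absolute
  refractory period. Across-unit collisions are allowed and produce a small
  irreducible false-negative floor (~1 % at 8 Hz total with 1 ms matching) —
  real benchmarks share this property.
* **Background noise**: Gaussian, with a dominant low-frequency neural
  component (white noise shaped by a 2nd-order Butterworth low-pass at
  500 Hz, carrying 95 % of the in-band power) over a white thermal floor;
  `noise_sd` (default 20 µV) fixes the standard deviation *after* the
  200–3000 Hz detection band-pass — the scale the threshold estimator sees.
  Two properties motivated this over flat white noise. Keeping the mixture
  Gaussian keeps the median-based σ_N estimator exact. Concentrating power
  at the low edge of the spike band reflects real extracellular spectra,
  which fall steeply with frequency, and brings the rate of noise-only
  threshold crossings down toward what real benchmarks exhibit: for a
  Gaussian process the rate of |x| excursions beyond 4σ is
  ν₀·e⁻⁸ with ν₀ the RMS bandwidth, so flat in-band noise (ν₀ ≈ 1.6 kHz)
  fires ~30 false events/min at an exact 4σ threshold — far more than
  high-accuracy benchmarks show — while the shaped background brings
  ν₀ down several-fold.

**What passing tests do and do not show.** The generator captures event
density, waveform diversity, detectability margins and a realistic
noise spectrum. It does not model non-Gaussian multiunit background,
electrode drift, bursting, or overlapping-spike resolution; detection
accuracy on this benchmark therefore isolates the effect of chain
distortion under near-ideal conditions and will overstate absolute accuracy
on difficult real recordings. Even here, two floors bound accuracy below
100 %: collision false negatives and residual noise crossings at the exact
4σ threshold. The sweep machinery measures distortion effects *relative*
to that baseline.

## 6. The spike pipeline

Band-pass: zero-phase 4th-order Butterworth, 200–3000 Hz. Threshold:
Thr = 4σ_N, σ_N = median(|x|)/0.6745. Detection: local minima below −Thr
— extracellular spikes are negative-going at the electrode, and
single-polarity detection halves the Gaussian false-crossing rate and
ignores template overshoots; a `"both"` polarity mode is available.
Crossings within 1 ms merge into one event (absolute refractory period).
Extraction uses a 5 ms window re-centered on the absolute peak
(peak-of-|x| synchronization), discarding windows that run off the record.
Features are projections on the leading eigenvectors of the mean-centered
waveform covariance; sorting is seeded Lloyd k-means on the scores, then
one reassignment pass in waveform space (each spike moves to the cluster
whose mean waveform gives smaller RMS error), with spikes beyond 3× their
cluster's median RMS error marked unclustered and removed from the sorted
count. The cluster count is set to the ground-truth template count in
experiments; cluster-number selection is out of scope.

Scoring matches detected to true events one-to-one within 1 ms (half a
typical spike width). The matching maximizes the number of pairs (dynamic
programming over the sorted sequences, exact per connected component) —
a greedy nearest-first pass can drop a feasible pair when two events
interleave within tolerance, which would miscount both an FP and an FN.
Precision, recall and accuracy = TP/(TP+FP+FN) follow, along with the
signed spike-count error against a level-0 baseline.

## 7. The decoding paradigm

A deliberately minimal stand-in for handwriting-trajectory decoding from
continuous neural features: 15 synthetic pen strokes (smoothed random
walks), a linear-Gaussian tuning model (96 channels, state = position and
velocity, 50 ms bins, constant-velocity transition), and a standard Kalman
filter, scored by the Pearson correlation between decoded and true
positions. None of the real paradigm's internals (channel counts, feature
definitions, bin widths) are published in a reproducible form; the module
documents its own defaults and exposes them as parameters.

Chain distortion is propagated to the observation streams in normalized
units: an amplifier level's settling/slew map depends only on
$\tau/T_s$ and $SR\,T_s/\mathrm{scale}$, so the same dimensionless map the
calibrated stage applies at 24 kHz is applied per channel at the bin rate
(`level_observation_map()`), and the converter contributes quantization
against its calibrated perturbed ladder. One ladder draw is shared across
levels — one physical converter with progressively worse matching — so
severity is nested. Each trial's observation noise is likewise drawn once
and shared across levels, because the paradigm passes the *same* data
through each distortion configuration; both choices make level comparisons
paired, which is what lets a monotone correlation ordering emerge from
small distortion contrasts.

## 8. Problem sizes and numerical conventions

* Tone records: 1 s at 24 kHz (coherent, 1109 cycles).
* Calibration: 36 bisection steps per target; ADC medians over 10 ladder
  draws.
* Detection experiments: 60 s records, medians over 10 benchmark
  repetitions; the full scenario × level sweep in the test suite uses 30 s
  records with 10 repetitions per cell, sizes chosen to keep a full run in
  minutes on one core while holding the median accuracy quantization to a
  fraction of a percentage point.
* Seeds: every stochastic element takes an explicit seed; drivers derive
  per-cell seeds as `base + scenario_index*1000 + rep`. Package RNG runs on
  a private stream and leaves the caller's `.Random.seed` untouched.
* k-means: seeded random-row initialization, Lloyd iterations to a 10⁻⁶
  centroid shift or 300 iterations.
* Kalman: innovations are exposed for whiteness checks; covariances are
  validated positive semi-definite.

## 9. Known limitations

* Behavioral, not circuit-level: no transistor netlists, temperature or
  corner effects, crosstalk, 1/f noise, comparator metastability or clock
  jitter.
* The three-case error model is sample-synchronous; its distortion depth
  depends on the model rate, so levels are calibrated and used at one rate.
* The case-1 error expression caps at SR·τ, so THD is not monotone in SR in
  the asymptotic deep-slew regime (Section 1.2).
* The benchmark's background is Gaussian; real recordings' non-Gaussian
  multiunit hash affects median-based thresholds in ways this generator
  only approximates spectrally.
* Absolute THD values for the amplifier ladder depend on unpublished
  circuit constants; the levels here are defined by their calibrated THD,
  not by claiming the original knob values.
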