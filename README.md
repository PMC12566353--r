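# spikechain

Behavioral simulation of non-linear neural recording chains and their impact
on spike processing accuracy.

Implantable multi-channel neural recording systems face a three-way trade-off
between linearity, power and circuit area: suppressing harmonic distortion in
the analog front end (low-noise amplifier, programmable gain amplifier) and
the analog-to-digital converter costs power and silicon, while too much
distortion corrupts the spike waveforms that downstream detection, sorting
and decoding depend on. `spikechain` is a desk-scale simulator for exploring
that trade-off: it models each stage of the chain behaviorally, injects
graded, calibrated amounts of non-linearity, and measures the consequences
with the field's standard instruments — single-tone linearity metrics,
ground-truth spike detection scoring, and a trajectory-decoding paradigm.

It is aimed at mixed-signal designers who want quantitative distortion
budgets ("how much THD can the ADC tolerate before detection accuracy
drops?") and at signal-processing researchers who need a controllable
test-bed with exact ground truth.

## The models

**Front end.** Each amplifier stage is a capacitive-feedback topology with
closed-loop transfer function (LNA)

    H(s) = (Cin/Cf) * [ -s Rf Cf / (1 + s Rf Cf) ] * 1 / (1 + s CL/(Gm beta))

with mid-band feedback coefficient `beta = Cf/(Cin+Cp+Cf)` and equivalent
load `CL = Cl + (1-beta) Cf`; the PGA is the corresponding low-pass stage
with gain C1/C2. Non-linearity enters through the OTA's large-signal limits:
with integration time constant `tau = 2 pi Cin Cl/(Gm Cf)`, slope
`|v|/tau` and slew rate SR, the per-sample settling error is

    case 1 (slope > SR, t_sl >= Ts/2):  error = |v| - SR * t_sl
    case 2 (slope > SR, t_sl <  Ts/2):  error = (|v| - SR * t_sl) * exp(-t_lin/tau)
    case 3 (slope <= SR):               error = |v| * exp(-Ts/(2 tau))

with `t_sl = |v|/SR - tau`. The error is subtracted from the stage output in
the direction of the signal change, so the output lags the ideal response;
lowering (GBW, SR) jointly along a constant SR/GBW ray deepens the harmonic
distortion monotonically. A white input-referred noise source with a
configurable PSD floor completes the stage.

**ADC.** An n-bit flash converter: 2^n - 1 comparator thresholds from a
resistor ladder, with static mismatch modeled as Gaussian perturbation of the
thresholds (re-sorted, as a bubble-corrected encoder behaves). This shapes
INL/DNL and hence harmonic distortion; quantization plus an optional thermal
noise floor set the noise. The ideal 12-bit chain realizes the textbook
SNR = 6.02 n + 1.76 dB on a full-scale coherent tone.

**Evaluation.** Single-tone records (1.11 kHz, 100 uV at the electrode) are
scored by FFT power accounting into SNR, THD, SNDR, SFDR and
ENOB = (SNDR - 1.76)/6.02. Synthetic annotated recordings (Poisson spike
trains, biphasic unit templates, neural-weighted Gaussian background)
feed the spike pipeline: 200-3000 Hz band-pass, adaptive threshold
`Thr = 4 sigma_N` with `sigma_N = median(|x|)/0.6745`, event detection,
5 ms peak-aligned extraction, PCA features, k-means sorting with
waveform-space reassignment, and TP/FP/FN scoring against ground truth
(accuracy = TP/(TP+FP+FN)). A linear-Gaussian tuning model plus Kalman
filter provides a minimal handwriting-style trajectory-decoding paradigm
scored by Pearson correlation.

## Worked example

Calibrate the converter's distortion ladder to the target THD anchors, then
measure detection accuracy with the level-2 converter in an otherwise linear
chain:

```r
library(spikechain)

## ideal 12-bit converter on a full-scale coherent tone
tone <- generate_test_tone(f0 = 1109, fs = 24000, duration = 1,
                           amplitude = 0.999 * 0.6)
tone_metrics(adc_chain(tone$signal, 24000, adc_params()), 24000, 1109)
#> Tone 1109 Hz: SNR 73.99 dB, THD -100.52 dB, SNDR 73.98 dB,
#>   SFDR 98.46 dB, ENOB 12.00 bits

## calibrate ladder perturbation to the distortion-level THD anchors
cal <- calibrate_levels("ADC", c(-68.44, -57.95, -44.42, -32.37), seed = 1)
cal
#> Distortion levels for ADC (tone 1109 Hz at 0.0001 V):
#>  level target_thd_db       knob achieved_thd_db  met
#>      0            NA         NA              NA TRUE
#>      1        -68.44   8.109991       -68.43930 TRUE
#>      2        -57.95  21.883544       -57.94968 TRUE
#>      3        -44.42  76.663007       -44.41997 TRUE
#>      4        -32.37 307.296948       -32.36999 TRUE

## spike detection through the chain with the level-2 converter
rec <- make_benchmark(reduced_preset(), seed = 1)   # 60 s, 3 units, ~8 Hz
res <- run_detection(rec, adc = params_at_level(cal, 2, seed = 1))
res$report
#> TP 471, FP 10, FN 6 | precision 0.979, recall 0.987, accuracy 0.967
```

The SNR of 73.99 dB and ENOB of 12.00 bits are the quantization-limited
ceiling of a 12-bit converter; the calibration finds the ladder-mismatch
amplitude (in LSB) that lands each THD anchor; and at the −57.95 dB
distortion level detection accuracy stays near 97 % — moderate converter
non-linearity is essentially free at this task.

The same machinery sweeps whole scenarios: `run_sweep()` crosses
{LNA, PGA, front-end, ADC, all} with levels 0-4 over repeated benchmark
draws, `resolution_sweep()` varies converter resolution with an ideal
ladder, and `decode_experiment()` propagates calibrated distortion into the
trajectory-decoding paradigm.

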