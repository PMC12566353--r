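## Shared fixtures for the spikechain test suite.

## Distortion-level calibrations are expensive enough to compute once per
## session; targets are the per-stage THD anchors of the distortion ladder.
.cal_cache <- new.env(parent = emptyenv())
get_cal <- function(stage) {
  if (is.null(.cal_cache[[stage]])) {
    targets <- switch(stage,
      LNA = c(-46.56, -40.93, -34.32, -26.23),
      PGA = c(-50.21, -42.42, -33.73, -24.27),
      ADC = c(-68.44, -57.95, -44.42, -32.37))
    .cal_cache[[stage]] <- calibrate_levels(stage, targets, seed = 1)
  }
  .cal_cache[[stage]]
}

## 1 s coherent test tone at the standard frequency (1109 Hz: nearest
## prime-cycle coherent frequency to 1.11 kHz for a 24000-sample record)
std_tone <- function(amplitude = 100e-6) {
  generate_test_tone(f0 = 1109, amplitude = amplitude, fs = 24000,
                     duration = 1)
}

## LNA parameters with a prescribed integration time constant (default
## geometry: tau = 0.1 / GBW)
lna_with_tau <- function(tau, SR = NULL, noise_floor = 0) {
  lna_params(GBW = 100 / tau, SR = SR, noise_floor = noise_floor)
}

## Exhaustive enumeration oracle for event matching: maximum number of
## one-to-one pairs within tolerance, trying every assignment of each
## detected event to a compatible truth event (or none).
oracle_match_count <- function(detected, truth, tol) {
  n <- length(detected)
  recurse <- function(i, used) {
    if (i > n) return(0L)
    best <- recurse(i + 1L, used)  # leave detected[i] unmatched
    for (j in seq_along(truth)) {
      if (!used[j] && abs(detected[i] - truth[j]) <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, logical(length(truth)))
}
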