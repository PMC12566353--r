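#' Flash ADC parameters
#'
#' An n-bit flash converter compares the input against 2^n - 1 reference
#' levels generated by a resistor ladder. Static resistor mismatch is modeled
#' by Gaussian perturbation of the ideal thresholds, which is the converter's
#' tunable non-linearity (it shapes INL/DNL and hence harmonic distortion).
#'
#' @param n_bits resolution in bits (2-16; 8-14 are the practically relevant
#'   range, default 12)
#' @param v_min,v_max reference range (V)
#' @param perturb_sigma standard deviation of the threshold perturbation, in
#'   fractions of one LSB; 0 gives the ideal ladder
#' @param noise_floor one-sided thermal-noise PSD at the ADC input (V^2/Hz)
#' @param seed integer seed for the (static) ladder draw
#' @return an object of class `adc_params`
#' @export
adc_params <- function(n_bits = 12, v_min = -0.6, v_max = 0.6,
                       perturb_sigma = 0, noise_floor = 0, seed = 0) {
  stopifnot(n_bits >= 2, n_bits <= 16, v_max > v_min, perturb_sigma >= 0,
            noise_floor >= 0)
  structure(list(n_bits = as.integer(n_bits), v_min = v_min, v_max = v_max,
                 perturb_sigma = perturb_sigma, noise_floor = noise_floor,
                 seed = seed),
            class = "adc_params")
}

#' @export
print.adc_params <- function(x, ...) {
  cat(sprintf("%d-bit flash ADC, range [%.3g, %.3g] V, LSB %.3g V\n",
              x$n_bits, x$v_min, x$v_max,
              (x$v_max - x$v_min) / 2^x$n_bits))
  cat(sprintf("  ladder perturbation sigma %.3g LSB, thermal floor %.3g V^2/Hz\n",
              x$perturb_sigma, x$noise_floor))
  invisible(x)
}

#' Build the (possibly perturbed) comparator reference ladder
#'
#' Ideal mid-rise thresholds t_i = v_min + i * LSB for i = 1 .. 2^n - 1 are
#' each shifted by N(0, (perturb_sigma * LSB)^2) and re-sorted; a flash
#' encoder with bubble-error correction behaves monotonically, so the sorted
#' ladder is the behavioral equivalent. The draw is static (resistor
#' mismatch), reproducible under the seed.
#'
#' @param params an [adc_params()] object
#' @return object of class `reference_ladder`: list with `thresholds`
#'   (strictly increasing, length 2^n - 1), `lsb`, `v_min`, `v_max`, `n_bits`
#' @export
build_reference_ladder <- function(params) {
  stopifnot(inherits(params, "adc_params"))
  n_levels <- 2^params$n_bits - 1
  lsb <- (params$v_max - params$v_min) / 2^params$n_bits
  ideal <- params$v_min + seq_len(n_levels) * lsb
  thr <- ideal
  if (params$perturb_sigma > 0) {
    rng <- local_rng(params$seed)
    thr <- sort(ideal + rng$rnorm(n_levels, sd = params$perturb_sigma * lsb))
  }
  structure(list(thresholds = thr, ideal = ideal, lsb = lsb,
                 v_min = params$v_min, v_max = params$v_max,
                 n_bits = params$n_bits),
            class = "reference_ladder")
}

#' Quantize a voltage series against a reference ladder
#'
#' Each sample's code is the number of ladder thresholds strictly below it
#' (thermometer-to-binary conversion). Codes lie in 0 .. 2^n - 1;
#' out-of-range inputs saturate at the end codes.
#'
#' @param x voltage series (V)
#' @param ladder a [build_reference_ladder()] result
#' @return integer code series
#' @export
quantize <- function(x, ladder) {
  stopifnot(inherits(ladder, "reference_ladder"))
  findInterval(x, ladder$thresholds, left.open = TRUE)
}

#' Reconstruct voltages from ADC codes
#'
#' Mid-tread reconstruction v = v_min + (code + 1/2) * LSB using the ideal
#' LSB: the digital back end does not know the ladder perturbation.
#'
#' @param codes integer code series
#' @param ladder a [build_reference_ladder()] result
#' @return voltage series (V)
#' @export
codes_to_voltage <- function(codes, ladder) {
  stopifnot(inherits(ladder, "reference_ladder"))
  if (any(codes < 0 | codes > 2^ladder$n_bits - 1)) {
    stop("codes out of range for this ladder")
  }
  ladder$v_min + (codes + 0.5) * ladder$lsb
}

#' Integral and differential non-linearity of a ladder
#'
#' DNL_i = (t_{i+1} - t_i)/LSB - 1 (2^n - 2 entries) and
#' INL_i = (t_i - t_i^ideal)/LSB (2^n - 1 entries). The telescoping identity
#' INL_{i+1} - INL_i = DNL_i holds exactly.
#'
#' @param ladder a [build_reference_ladder()] result
#' @return list with `inl` and `dnl`, both in LSB units
#' @export
inl_dnl <- function(ladder) {
  stopifnot(inherits(ladder, "reference_ladder"))
  inl <- (ladder$thresholds - ladder$ideal) / ladder$lsb
  dnl <- diff(ladder$thresholds) / ladder$lsb - 1
  list(inl = inl, dnl = dnl)
}

#' Full behavioral ADC chain
#'
#' Thermal noise is added at the input ([white_noise()] contract), the sum is
#' sampled-and-held, quantized against the (possibly perturbed) ladder and
#' reconstructed with the ideal LSB. Deterministic under the parameter seed.
#' A warning is raised when more than 1 % of samples saturate.
#'
#' @param x voltage series (V), nominally within the reference range
#' @param fs sampling rate (Hz)
#' @param params an [adc_params()] object
#' @return reconstructed voltage series
#' @export
adc_chain <- function(x, fs, params) {
  stopifnot(inherits(params, "adc_params"), fs > 0)
  ladder <- build_reference_ladder(params)
  if (params$noise_floor > 0) {
    x <- x + white_noise(length(x), params$noise_floor, fs, params$seed + 1L)
  }
  clipped <- mean(x < params$v_min | x > params$v_max)
  if (clipped > 0.01) {
    warning(sprintf("%.1f%% of samples saturate the ADC range",
                    100 * clipped))
  }
  codes_to_voltage(quantize(x, ladder), ladder)
}
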