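#' Run a signal through one amplifier stage model
#'
#' The stage comprises the discretized closed-loop linear response (bilinear
#' transform of [lna_closed_loop_tf()] or [pga_closed_loop_tf()] at the
#' working rate), a non-linearity module and a white-noise module:
#'
#' 1. input-referred white noise at `params$noise_floor` is added to the
#'    signal;
#' 2. the sum is filtered by the closed-loop response;
#' 3. if `params$SR` is set, the three-case slew/settling error (see
#'    [slew_error()]) is evaluated sample-wise on the instantaneous stage
#'    output and subtracted in the direction of the current signal change.
#'
#' With `SR` unset and `noise_floor = 0` the output is exactly the linear
#' filter response: distortion level 0. A warning of class
#' `"spikechain_alias_warning"` is raised when the stage's closed-loop
#' low-pass corner exceeds the Nyquist rate (the model's own pole is then
#' frequency-warped by the discretization).
#'
#' @param x input voltage series (V)
#' @param fs sampling rate (Hz)
#' @param params an [amp_params()] object
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_floor = 0`)
#' @return output voltage series, same length as `x`
#' @examples
#' tone <- generate_test_tone(fs = 24000, duration = 0.1)
#' out <- suppressWarnings(process_amplifier(tone$signal, 24000, lna_params(),
#'                                           seed = 1))
#' @export
process_amplifier <- function(x, fs, params, seed = 0) {
  stopifnot(inherits(params, "amp_params"), is.numeric(x), fs > 0)
  if (any(!is.finite(x))) stop("input signal must be finite")
  d <- compute_derived(params)
  corner <- params$Gm * d$beta / (2 * pi * d$CL_eff)
  if (corner > fs / 2) {
    warning(structure(
      class = c("spikechain_alias_warning", "warning", "condition"),
      list(message = sprintf(
        paste0("stage low-pass corner (%.3g Hz) exceeds Nyquist (%.3g Hz); ",
               "the discretized pole is frequency-warped"), corner, fs / 2),
        call = NULL)))
  }
  H <- if (params$role == "LNA") lna_closed_loop_tf(params) else {
    pga_closed_loop_tf(params)
  }
  if (params$noise_floor > 0) {
    x <- x + white_noise(length(x), params$noise_floor, fs, seed)
  }
  y <- apply_tf(H, x, fs)
  if (!is.null(params$SR)) {
    y <- inject_settling_error(y, d$tau, params$SR, 1 / fs)
  }
  y
}
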