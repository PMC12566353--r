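#' Three-case slew/settling error of an amplifier stage
#'
#' Classifies the stage response to a voltage excursion of magnitude
#' `vin_abs` within one sampling period and returns the residual error at the
#' sampling instant. The demanded slope is `vin_abs / tau` with
#' tau = 2 pi Cin Cl/(Gm Cf); `t_sl = vin_abs/SR - tau` (clipped at 0) is the
#' slewing time.
#'
#' * Case 1 (slope > SR and t_sl >= Ts/2): fully slew-limited,
#'   `error = vin_abs - SR * t_sl`.
#' * Case 2 (slope > SR and t_sl < Ts/2): slews then settles linearly for
#'   `t_lin = Ts/2 - t_sl`, `error = (vin_abs - SR * t_sl) * exp(-t_lin/tau)`.
#' * Case 3 (slope <= SR): purely linear settling,
#'   `error = vin_abs * exp(-Ts/(2 tau))`.
#'
#' Errors are magnitudes, clamped at zero from below. An unset slew rate
#' (`SR = NULL` in the parameters) is treated as infinite: case 3 always.
#'
#' @param vin_abs excursion magnitude (V), >= 0
#' @param params an [amp_params()] object (supplies tau and SR)
#' @param Ts sampling period (s)
#' @return list with `case_id` (1, 2 or 3), `slope` (V/s), `t_sl`, `t_lin`
#'   (s) and `error` (V)
#' @examples
#' p <- lna_params()
#' slew_error(100e-6, p, Ts = 1/24000)$case_id  # 3: no slew limiting
#' @export
slew_error <- function(vin_abs, params, Ts) {
  stopifnot(inherits(params, "amp_params"), vin_abs >= 0, Ts > 0)
  tau <- compute_derived(params)$tau
  SR <- if (is.null(params$SR)) Inf else params$SR
  if (SR <= 0) stop("'SR' must be positive")
  slope <- vin_abs / tau
  if (slope > SR) {
    t_sl <- max(vin_abs / SR - tau, 0)
    if (t_sl >= Ts / 2) {
      list(case_id = 1L, slope = slope, t_sl = t_sl, t_lin = 0,
           error = max(vin_abs - SR * t_sl, 0))
    } else {
      t_lin <- Ts / 2 - t_sl
      list(case_id = 2L, slope = slope, t_sl = t_sl, t_lin = t_lin,
           error = max((vin_abs - SR * t_sl) * exp(-t_lin / tau), 0))
    }
  } else {
    list(case_id = 3L, slope = slope, t_sl = 0, t_lin = Ts / 2,
         error = vin_abs * exp(-Ts / (2 * tau)))
  }
}

## Vectorized error injection used by process_amplifier: evaluates the
## three-case error on the instantaneous stage output magnitude (the
## non-linearity module sits after the gain stage) and subtracts it in the
## direction of the current signal change, so the output lags the ideal
## response. Feed-forward, so the fundamental of a tone is preserved while
## harmonics grow as tau increases or SR decreases.
inject_settling_error <- function(v, tau, SR, Ts) {
  av <- abs(v)
  slope <- av / tau
  t_sl <- pmax(av / SR - tau, 0)
  slewing <- slope > SR
  err <- ifelse(
    slewing,
    ifelse(t_sl >= Ts / 2,
           av - SR * t_sl,
           (av - SR * t_sl) * exp(-(Ts / 2 - t_sl) / tau)),
    av * exp(-Ts / (2 * tau))
  )
  err <- pmax(err, 0)
  dv <- diff(v)
  dir <- sign(c(if (length(v)) v[1] else numeric(0), dv))
  v - dir * err
}
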