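#' Amplifier stage parameters
#'
#' Describes one capacitive-feedback amplifier stage (LNA or PGA) of the
#' recording front end: coupling capacitances, OTA transconductance,
#' gain-bandwidth product (GBW), slew rate (SR) and the white input-referred
#' noise floor. For the PGA read `Cin` as the input capacitance C1, `Cf` as
#' the programmable feedback capacitance C2 and `Rf` as the feedback
#' resistance R1.
#'
#' Consistency rules enforced when redundant values are supplied:
#' GBW = Gm/(2 pi Cl) and SR/GBW = 4 pi Ids/Gm, both within 1 %.
#' When `Gm` is omitted it is derived from `GBW`; when `SR` is omitted the
#' stage has no slew limiting and its non-linearity module is disabled.
#'
#' @param Cin input capacitance (F)
#' @param Cf feedback capacitance (F)
#' @param Cl load capacitance (F)
#' @param Cp parasitic capacitance at the summing node (F)
#' @param Rf pseudo-resistor feedback resistance (Ohm); sets the high-pass
#'   corner 1/(2 pi Rf Cf)
#' @param Gm OTA transconductance (A/V); derived from `GBW` if missing
#' @param Ro equivalent OTA output resistance (Ohm)
#' @param GBW gain-bandwidth product (Hz); derived from `Gm` if missing
#' @param SR slew rate (V/s), or `NULL` for no slew limiting
#' @param Ids drain-source current (A); if given, checked against
#'   SR/GBW = 4 pi Ids/Gm
#' @param noise_floor one-sided white input-referred noise PSD (V^2/Hz)
#' @param role `"LNA"` or `"PGA"`
#' @return an object of class `amp_params`
#' @examples
#' p <- amp_params(Cin = 20e-12, Cf = 200e-15, Cl = 1e-12, GBW = 10e6,
#'                 role = "LNA")
#' compute_derived(p)$midband_gain  # 100
#' @export
amp_params <- function(Cin, Cf, Cl, Cp = 0, Rf = 10e9, Gm = NULL, Ro = 5e8,
                       GBW = NULL, SR = NULL, Ids = NULL, noise_floor = 0,
                       role = c("LNA", "PGA")) {
  role <- match.arg(role)
  if (is.null(Gm) && is.null(GBW)) {
    stop("supply at least one of Gm and GBW")
  }
  if (is.null(Gm)) Gm <- 2 * pi * Cl * GBW
  if (is.null(GBW)) GBW <- Gm / (2 * pi * Cl)
  for (nm in c("Cin", "Cf", "Cl", "Rf", "Gm", "Ro", "GBW")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a positive finite scalar")
    }
  }
  if (Cp < 0) stop("parameter 'Cp' must be non-negative")
  if (noise_floor < 0) stop("'noise_floor' must be non-negative")
  if (!is.null(SR)) {
    if (!is.finite(SR) || SR <= 0) stop("'SR' must be positive (or NULL)")
  }
  if (abs(GBW - Gm / (2 * pi * Cl)) > 0.01 * GBW) {
    stop("inconsistent parameters: GBW must equal Gm/(2*pi*Cl) within 1%")
  }
  if (!is.null(Ids) && !is.null(SR)) {
    if (abs(SR / GBW - 4 * pi * Ids / Gm) > 0.01 * (SR / GBW)) {
      stop("inconsistent parameters: SR/GBW must equal 4*pi*Ids/Gm within 1%")
    }
  }
  structure(list(Cin = Cin, Cf = Cf, Cl = Cl, Cp = Cp, Rf = Rf, Gm = Gm,
                 Ro = Ro, GBW = GBW, SR = SR, Ids = Ids,
                 noise_floor = noise_floor, role = role),
            class = "amp_params")
}

#' @export
print.amp_params <- function(x, ...) {
  cat(sprintf("%s stage: gain %.1f (%.1f dB), GBW %.3g Hz, SR %s\n",
              x$role, x$Cin / x$Cf, 20 * log10(x$Cin / x$Cf), x$GBW,
              if (is.null(x$SR)) "unset (linear)" else sprintf("%.3g V/s", x$SR)))
  cat(sprintf("  Cin %.3g F, Cf %.3g F, Cl %.3g F, Rf %.3g Ohm, Gm %.3g A/V\n",
              x$Cin, x$Cf, x$Cl, x$Rf, x$Gm))
  cat(sprintf("  noise floor %.3g V^2/Hz\n", x$noise_floor))
  invisible(x)
}

#' Default LNA parameters
#'
#' 40 dB mid-band gain (Cin = 20 pF, Cf = 200 fF), GBW 10 MHz with a 1 pF
#' load (Gm ~ 62.8 uA/V), 10 GOhm pseudo-resistor (high-pass corner ~80 Hz).
#' The noise floor is set so a 100 uV test tone yields a stage SNR of about
#' 32.4 dB at a 24 kHz simulation rate.
#'
#' @param ... overrides passed to [amp_params()]
#' @return `amp_params` with `role = "LNA"`
#' @export
lna_params <- function(...) {
  args <- list(Cin = 20e-12, Cf = 200e-15, Cl = 1e-12, Cp = 0, Rf = 10e9,
               GBW = 10e6, Ro = 5e8, noise_floor = 2.51e-16, role = "LNA")
  override <- list(...)
  args[names(override)] <- override
  do.call(amp_params, args)
}

#' Default PGA parameters
#'
#' 20 dB gain (C1 = 2 pF, C2 = 200 fF), GBW 0.8 MHz with a 1 pF load. Noise
#' floor set for a stage SNR of about 33.1 dB on the standard 100 uV tone.
#'
#' @param ... overrides passed to [amp_params()]
#' @return `amp_params` with `role = "PGA"`
#' @export
pga_params <- function(...) {
  args <- list(Cin = 2e-12, Cf = 200e-15, Cl = 1e-12, Cp = 0, Rf = 10e9,
               GBW = 0.8e6, Ro = 5e8, noise_floor = 2.30e-16, role = "PGA")
  override <- list(...)
  args[names(override)] <- override
  do.call(amp_params, args)
}

#' Derived small-signal quantities of an amplifier stage
#'
#' Computes the mid-band feedback coefficient beta = Cf/(Cin + Cp + Cf), the
#' equivalent load CL = Cl + (1 - beta) Cf, the integration time constant
#' tau = 2 pi Cin Cl/(Gm Cf) and the mid-band closed-loop gain Cin/Cf.
#'
#' @param params an [amp_params()] object
#' @return list with `beta`, `CL_eff`, `tau`, `midband_gain`
#' @export
compute_derived <- function(params) {
  stopifnot(inherits(params, "amp_params"))
  beta <- params$Cf / (params$Cin + params$Cp + params$Cf)
  CL_eff <- params$Cl + (1 - beta) * params$Cf
  tau <- 2 * pi * params$Cin * params$Cl / (params$Gm * params$Cf)
  list(beta = beta, CL_eff = CL_eff, tau = tau,
       midband_gain = params$Cin / params$Cf)
}

#' Closed-loop LNA transfer function
#'
#' H(s) = (Cin/Cf) * (-s Rf Cf/(1 + s Rf Cf)) * 1/(1 + s CL/(Gm beta)), the
#' deep-feedback approximation of the capacitive-feedback topology: a
#' high-pass zero at DC from the pseudo-resistor, mid-band gain Cin/Cf
#' (inverting) and a low-pass pole set by the loop bandwidth. `beta` is taken
#' at its mid-band limit Cf/(Cin + Cp + Cf).
#'
#' @param params an [amp_params()] object with `role = "LNA"`
#' @return a [ctf()] object
#' @examples
#' H <- lna_closed_loop_tf(lna_params())
#' tf_gain_db(H, 1e3)  # ~40 dB
#' @export
lna_closed_loop_tf <- function(params) {
  stopifnot(inherits(params, "amp_params"))
  if (params$role != "LNA") stop("expected LNA parameters")
  d <- compute_derived(params)
  g0 <- params$Cin / params$Cf
  ## (-s Rf Cf) / (1 + s Rf Cf)
  hp_num <- c(0, -params$Rf * params$Cf)
  hp_den <- c(1, params$Rf * params$Cf)
  ## 1 / (1 + s CL/(Gm beta))
  lp_den <- c(1, d$CL_eff / (params$Gm * d$beta))
  ctf(g0 * hp_num, poly_mul(hp_den, lp_den))
}

#' Closed-loop PGA transfer function
#'
#' H(s) = -(C1/C2) / (1 + s CL2/(Gm2 betaP)): a low-pass stage with DC gain
#' equal to the capacitor ratio.
#'
#' @param params an [amp_params()] object with `role = "PGA"`
#' @return a [ctf()] object
#' @export
pga_closed_loop_tf <- function(params) {
  stopifnot(inherits(params, "amp_params"))
  if (params$role != "PGA") stop("expected PGA parameters")
  d <- compute_derived(params)
  ctf(-params$Cin / params$Cf, c(1, d$CL_eff / (params$Gm * d$beta)))
}

#' Open-loop LNA transfer function
#'
#' H(s) = Gm Ro beta / (1 + s Ro CL), valid when the pseudo-resistor is much
#' larger than the OTA output resistance (the feedback-loading term is
#' dropped).
#'
#' @param params an [amp_params()] object with `role = "LNA"`
#' @return a [ctf()] object
#' @export
lna_open_loop_tf <- function(params) {
  stopifnot(inherits(params, "amp_params"))
  if (params$role != "LNA") stop("expected LNA parameters")
  d <- compute_derived(params)
  ctf(params$Gm * params$Ro * d$beta, c(1, params$Ro * d$CL_eff))
}

#' Transconductance needed for a target gain-bandwidth product
#'
#' The sizing identity GBW = gm/(2 pi CL), solved for gm. With GBW = 10 MHz
#' and CL = 1 pF this gives approximately 62.8 uA/V.
#'
#' @param gbw target gain-bandwidth product (Hz)
#' @param cl load capacitance (F)
#' @return transconductance in A/V
#' @export
gm_for_gbw <- function(gbw, cl) {
  stopifnot(gbw > 0, cl > 0)
  2 * pi * gbw * cl
}

#' Slew-rate to gain-bandwidth ratio of an OTA
#'
#' SR/GBW = 4 pi Ids/Gm, the large-signal/small-signal speed ratio of a
#' single-stage OTA.
#'
#' @param Ids drain-source (tail) current (A)
#' @param Gm transconductance (A/V)
#' @return the ratio SR/GBW in volts
#' @export
sr_gbw_ratio <- function(Ids, Gm) {
  stopifnot(Ids > 0, Gm > 0)
  4 * pi * Ids / Gm
}
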