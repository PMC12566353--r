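#' Linear-Gaussian tuning model for trajectory decoding
#'
#' A minimal stand-in for an ESA-based (entire spiking activity) handwriting
#' decoder: `n_channels` continuous observation channels are linear-Gaussian
#' functions of the kinematic state (x, y, vx, vy) with a constant-velocity
#' state transition, decoded by a standard Kalman filter.
#'
#' @param n_channels number of observation channels (default 96)
#' @param bin_s bin width in seconds (default 0.05)
#' @param obs_noise_sd per-channel observation noise sd (default 0.5, in
#'   units of the channel tuning scale)
#' @param process_noise_sd process (acceleration) noise sd per bin
#' @param seed integer seed for the random tuning directions
#' @return object of class `tuning_model`: list with `H` (channels x 4), `R`
#'   (channels x channels), `A` (4 x 4), `Q` (4 x 4), `bin_s`
#' @export
tuning_model <- function(n_channels = 96, bin_s = 0.05, obs_noise_sd = 0.5,
                         process_noise_sd = 0.15, seed = 0) {
  stopifnot(n_channels >= 4, bin_s > 0, obs_noise_sd >= 0)
  rng <- local_rng(seed)
  ## random position+velocity tuning per channel, unit-norm rows
  H <- matrix(rng$rnorm(n_channels * 4), n_channels, 4)
  H <- H / sqrt(rowSums(H^2))
  A <- diag(4)
  A[1, 3] <- bin_s
  A[2, 4] <- bin_s
  Q <- diag(c(1e-6, 1e-6, process_noise_sd^2, process_noise_sd^2))
  R <- diag(rep(obs_noise_sd^2, n_channels))
  structure(list(H = H, R = R, A = A, Q = Q, bin_s = bin_s),
            class = "tuning_model")
}

#' Simulate observation streams from a 2-D trajectory
#'
#' The kinematic state per bin is (x, y, vx, vy) with velocities from finite
#' differences of the trajectory; observations are H state + N(0, R).
#'
#' @param trajectory n_bins x 2 matrix of positions
#' @param model a [tuning_model()]
#' @param seed integer seed for the observation noise
#' @return list with `obs` (channels x bins) and `state` (4 x bins)
#' @export
simulate_observations <- function(trajectory, model, seed = 0) {
  stopifnot(inherits(model, "tuning_model"), ncol(trajectory) == 2)
  nb <- nrow(trajectory)
  v <- rbind(c(0, 0), diff(trajectory)) / model$bin_s
  state <- t(cbind(trajectory, v))  # 4 x bins
  obs <- model$H %*% state
  sds <- sqrt(diag(model$R))
  if (any(sds > 0)) {
    rng <- local_rng(seed)
    obs <- obs + matrix(rng$rnorm(length(obs)), nrow(obs)) * sds
  }
  list(obs = obs, state = state)
}

#' Kalman-filter decoding of a 2-D trajectory from observations
#'
#' Standard predict/update recursion under the tuning model; returns the
#' filtered position estimates. The innovation sequence is also returned for
#' whiteness diagnostics.
#'
#' @param obs channels x bins observation matrix
#' @param model a [tuning_model()]
#' @param x0 initial state (default zeros), `P0` initial covariance
#' @param P0 initial state covariance (default 10 I)
#' @return list with `trajectory` (bins x 2), `state` (4 x bins),
#'   `innovations` (channels x bins)
#' @export
kalman_decode <- function(obs, model, x0 = rep(0, 4), P0 = diag(4) * 10) {
  stopifnot(inherits(model, "tuning_model"))
  ev_r <- eigen(model$R, symmetric = TRUE, only.values = TRUE)$values
  ev_q <- eigen(model$Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_r) < -1e-12 || min(ev_q) < -1e-12) {
    stop("R and Q must be positive semi-definite")
  }
  H <- model$H
  A <- model$A
  Q <- model$Q
  R <- model$R
  nb <- ncol(obs)
  xs <- matrix(0, 4, nb)
  innov <- matrix(0, nrow(obs), nb)
  x <- x0
  P <- P0
  for (k in seq_len(nb)) {
    xp <- A %*% x
    Pp <- A %*% P %*% t(A) + Q
    S <- H %*% Pp %*% t(H) + R
    K <- Pp %*% t(H) %*% solve(S)
    y <- obs[, k] - H %*% xp
    x <- xp + K %*% y
    P <- (diag(4) - K %*% H) %*% Pp
    xs[, k] <- x
    innov[, k] <- y
  }
  list(trajectory = t(xs[1:2, , drop = FALSE]), state = xs,
       innovations = innov)
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation between two equal-length series.
#'
#' @param a,b numeric vectors, length >= 3, non-constant
#' @return correlation in \[-1, 1\]
#' @export
pearson_cc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) stop("constant input has undefined correlation")
  mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b)) *
    length(a) / (length(a) - 1)
}

#' Generate smooth synthetic pen strokes
#'
#' Smoothed random walks standing in for handwriting trajectories: Gaussian
#' velocity increments smoothed by a moving average, integrated to position.
#'
#' @param n_trials number of strokes
#' @param n_bins bins per stroke
#' @param seed integer seed
#' @return list of n_bins x 2 position matrices
#' @export
generate_strokes <- function(n_trials = 15, n_bins = 100, seed = 0) {
  rng <- local_rng(seed)
  lapply(seq_len(n_trials), function(i) {
    v <- matrix(rng$rnorm(2 * (n_bins + 20)), ncol = 2)
    sm <- apply(v, 2, function(col) {
      as.numeric(stats::filter(col, rep(1 / 10, 10), sides = 1))
    })
    sm <- sm[21:(n_bins + 20), ]
    pos <- apply(sm, 2, cumsum)
    pos - matrix(colMeans(pos), n_bins, 2, byrow = TRUE)
  })
}

## Dimensionless chain distortion applied to observation streams. Amplifier
## stages contribute the same three-case settling/slew error map they apply
## at their native rate, expressed in units of the observation bin time and
## signal scale (tau/Ts and SR*Ts/scale are preserved); the ADC contributes
## quantization against its (perturbed) ladder scaled to the observation
## range. `spec` is a list with optional elements `lna`, `pga` (each a
## `level_observation_map()` result) and `adc` (list with `perturb_sigma`,
## `n_bits`, `seed`). NULL spec = identity.
distort_observations <- function(obs, spec) {
  if (is.null(spec)) return(obs)
  scale <- max(abs(obs))
  if (scale == 0) return(obs)
  x <- obs / scale
  for (st in list(spec$lna, spec$pga)) {
    if (is.null(st)) next
    x <- t(apply(x, 1, function(ch) {
      inject_settling_error(ch, tau = st$tau_rel, SR = st$sr_rel, Ts = 1)
    }))
  }
  if (!is.null(spec$adc)) {
    p <- adc_params(n_bits = spec$adc$n_bits, v_min = -1.2, v_max = 1.2,
                    perturb_sigma = spec$adc$perturb_sigma,
                    seed = if (is.null(spec$adc$seed)) 0 else spec$adc$seed)
    ladder <- build_reference_ladder(p)
    x <- matrix(codes_to_voltage(quantize(x, ladder), ladder),
                nrow(x), ncol(x))
  }
  x * scale
}

#' Decode synthetic strokes through graded observation distortion
#'
#' Runs the full paradigm: `n_trials` synthetic strokes are encoded by the
#' tuning model, the observation streams are passed through the stage
#' distortion map at each requested level (level 0 = clean), decoded by the
#' Kalman filter, and scored by the Pearson correlation between decoded and
#' true positions (averaged over x and y).
#'
#' @param levels list of per-level distortion settings: each `NULL` (clean)
#'   or a list with optional elements `lna`, `pga` (each a
#'   [level_observation_map()] result) and `adc` (list with `perturb_sigma`,
#'   `n_bits`, `seed`); see [decode_levels_from_cal()]
#' @param n_trials number of strokes (default 15)
#' @param n_bins bins per stroke
#' @param model a [tuning_model()]; default built with the given seed
#' @param seed integer base seed
#' @return data.frame with columns `level`, `trial`, `cc_x`, `cc_y`,
#'   `cc_mean`
#' @export
decode_experiment <- function(levels, n_trials = 15, n_bins = 100,
                              model = NULL, seed = 0) {
  if (is.null(model)) model <- tuning_model(seed = seed)
  strokes <- generate_strokes(n_trials, n_bins, seed = seed + 1)
  out <- list()
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    for (tr in seq_len(n_trials)) {
      ## same observation draw for every level: the paradigm passes the
      ## same trial data through each distortion configuration
      sim <- simulate_observations(strokes[[tr]], model, seed = seed + tr)
      obs <- distort_observations(sim$obs, lv)
      dec <- kalman_decode(obs, model)
      ccx <- pearson_cc(dec$trajectory[, 1], strokes[[tr]][, 1])
      ccy <- pearson_cc(dec$trajectory[, 2], strokes[[tr]][, 2])
      out[[length(out) + 1L]] <- data.frame(
        level = li - 1L, trial = tr, cc_x = ccx, cc_y = ccy,
        cc_mean = (ccx + ccy) / 2)
    }
  }
  do.call(rbind, out)
}

#' Observation-domain distortion settings for a calibrated stage level
#'
#' Converts a calibrated amplifier level's (tau, SR) at its native sampling
#' rate into the dimensionless pair used by [decode_experiment()]:
#' `tau_rel = tau * fs` (tau in sample times) and
#' `sr_rel = SR / (fs * scale)` (slew limit in signal scales per sample).
#' This preserves the stage's sample-synchronous error geometry — the same
#' non-linear map in normalized units.
#'
#' @param tau stage time constant (s)
#' @param SR stage slew rate (V/s)
#' @param fs stage sampling rate (Hz)
#' @param scale stage signal amplitude (V) the tone test used
#' @return list with `tau_rel`, `sr_rel`
#' @export
level_observation_map <- function(tau, SR, fs, scale) {
  stopifnot(tau > 0, SR > 0, fs > 0, scale > 0)
  list(tau_rel = tau * fs, sr_rel = SR / (fs * scale))
}

#' Build decode-experiment distortion levels from stage calibrations
#'
#' For each level, the LNA and PGA contribute their calibrated settling/slew
#' maps in normalized units and the ADC contributes its calibrated ladder
#' perturbation; level 0 is clean.
#'
#' @param cal_lna,cal_pga,cal_adc [calibrate_levels()] results (any may be
#'   `NULL` to leave that stage out)
#' @param levels integer levels to include (default 0:4)
#' @param seed ladder seed for the ADC draw
#' @return list suitable for [decode_experiment()]'s `levels` argument
#' @export
decode_levels_from_cal <- function(cal_lna = NULL, cal_pga = NULL,
                                   cal_adc = NULL, levels = 0:4, seed = 1) {
  lapply(levels, function(lv) {
    if (lv == 0) return(NULL)
    spec <- list()
    for (nm in c("lna", "pga")) {
      cal <- if (nm == "lna") cal_lna else cal_pga
      if (is.null(cal)) next
      p <- params_at_level(cal, lv)
      d <- compute_derived(p)
      gain <- d$midband_gain
      spec[[nm]] <- level_observation_map(
        d$tau, p$SR, cal$fs, scale = cal$tone_amplitude * gain)
    }
    if (!is.null(cal_adc)) {
      row <- cal_adc$table[cal_adc$table$level == lv, ]
      ## one ladder draw shared across levels: the same mismatch pattern
      ## scaled by the perturbation amplitude, so severity is nested
      spec$adc <- list(perturb_sigma = row$knob,
                       n_bits = cal_adc$base$n_bits, seed = seed)
    }
    spec
  })
}
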