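#' Calibrate graded distortion levels for a stage
#'
#' Distortion levels are defined operationally by the THD a stage produces
#' on the standard 100 uV test tone. For the amplifiers the knob is a scale
#' factor g applied jointly to (GBW, SR) along a ray of constant SR/GBW
#' ratio (lowering g raises tau and lowers the slew limit together, which
#' monotonically deepens distortion); for the ADC the knob is the
#' reference-ladder perturbation amplitude in LSB. A scalar bisection finds
#' the knob matching each THD target; ADC THD is the median over
#' `n_seeds` independent ladder draws. Targets that cannot be met within the
#' knob bounds are reported with `met = FALSE` and the best value found.
#'
#' Amplifier calibration runs with the stage noise floor disabled: the
#' injected distortion is deterministic and the noise floor only biases the
#' spectral estimate.
#'
#' @param stage `"LNA"`, `"PGA"` or `"ADC"`
#' @param targets vector of THD targets in dB (negative, increasing toward
#'   0 = increasingly distorted), one per level 1..length(targets)
#' @param fs model sampling rate (Hz), default 24 kHz
#' @param f0 tone frequency; default the nearest coherent prime-cycle
#'   frequency to 1.11 kHz for a 1 s record
#' @param tone_amplitude tone amplitude at the stage input (V)
#' @param seed base seed for the ADC ladder draws
#' @param n_seeds ladder draws per ADC evaluation (median THD), default 10
#' @param tol_db acceptance tolerance on the achieved THD (dB), default 1.5
#' @param sr_gbw_ratio the constant SR/GBW ratio of the amplifier ray (V);
#'   default 1e-4 (the slew-to-bandwidth ratio of the nominal LNA design)
#' @return object of class `distortion_levels`: list with `stage`, `table`
#'   (data.frame: level, target_thd_db, knob, achieved_thd_db, met), `fs`,
#'   `f0`, and the stage base parameters
#' @export
calibrate_levels <- function(stage = c("LNA", "PGA", "ADC"), targets,
                             fs = 24000, f0 = NULL,
                             tone_amplitude = 100e-6, seed = 1,
                             n_seeds = 10, tol_db = 1.5,
                             sr_gbw_ratio = 1e-4) {
  stage <- match.arg(stage)
  if (length(targets) > 1 && any(diff(targets) <= 0)) {
    stop("THD targets must be strictly increasing toward 0")
  }
  n_rec <- fs  # 1 s record
  if (is.null(f0)) f0 <- coherent_tone_freq(fs, n_rec, 1110)
  tone <- generate_test_tone(f0 = f0, amplitude = tone_amplitude, fs = fs,
                             duration = n_rec / fs)
  base <- switch(stage, LNA = lna_params(), PGA = pga_params(),
                 ADC = adc_params())

  thd_of <- function(knob) {
    if (stage == "ADC") {
      amp_fs <- 0.999 * (base$v_max - base$v_min) / 2
      x <- tone$signal / tone_amplitude * amp_fs
      med <- median(vapply(seq_len(n_seeds), function(i) {
        p <- adc_params(n_bits = base$n_bits, v_min = base$v_min,
                        v_max = base$v_max, perturb_sigma = knob,
                        seed = seed + i)
        y <- adc_chain(x, fs, p)
        tone_metrics(y, fs, f0)$thd_db
      }, numeric(1)))
      med
    } else {
      p <- amp_at_scale(base, knob, sr_gbw_ratio)
      p$noise_floor <- 0
      y <- muffle_alias(process_amplifier(tone$signal, fs, p, seed = 0))
      tone_metrics(y, fs, f0)$thd_db
    }
  }

  bounds <- if (stage == "ADC") log(c(1e-3, 500)) else log(c(0.05, 50))
  rows <- lapply(seq_along(targets), function(i) {
    tgt <- targets[i]
    ## bisection on the log-knob; THD is monotone increasing as the ADC
    ## knob grows / the amplifier scale shrinks
    lo <- bounds[1]
    hi <- bounds[2]
    f_lo <- thd_of(knob_from(stage, lo))
    f_hi <- thd_of(knob_from(stage, hi))
    increasing <- f_hi > f_lo
    met <- TRUE
    if ((tgt < min(f_lo, f_hi)) || (tgt > max(f_lo, f_hi))) {
      met <- FALSE
      k <- if (abs(tgt - f_lo) < abs(tgt - f_hi)) knob_from(stage, lo) else {
        knob_from(stage, hi)
      }
      ach <- thd_of(k)
    } else {
      for (it in 1:36) {
        mid <- (lo + hi) / 2
        fm <- thd_of(knob_from(stage, mid))
        if ((fm < tgt) == increasing) lo <- mid else hi <- mid
      }
      k <- knob_from(stage, (lo + hi) / 2)
      ach <- thd_of(k)
      met <- abs(ach - tgt) <= tol_db
    }
    data.frame(level = i, target_thd_db = tgt, knob = k,
               achieved_thd_db = ach, met = met)
  })
  table <- rbind(
    data.frame(level = 0, target_thd_db = NA_real_, knob = NA_real_,
               achieved_thd_db = NA_real_, met = TRUE),
    do.call(rbind, rows))
  structure(list(stage = stage, table = table, fs = fs, f0 = f0,
                 tone_amplitude = tone_amplitude, base = base,
                 sr_gbw_ratio = sr_gbw_ratio, seed = seed),
            class = "distortion_levels")
}

knob_from <- function(stage, logk) exp(logk)

## Scale an amplifier's (GBW, SR) jointly: GBW = g * GBW0, SR = ratio * GBW.
amp_at_scale <- function(base, g, ratio) {
  gbw <- base$GBW * g
  amp_params(Cin = base$Cin, Cf = base$Cf, Cl = base$Cl, Cp = base$Cp,
             Rf = base$Rf, Ro = base$Ro, GBW = gbw, SR = ratio * gbw,
             noise_floor = base$noise_floor, role = base$role)
}

#' @export
print.distortion_levels <- function(x, ...) {
  cat(sprintf("Distortion levels for %s (tone %.4g Hz at %.3g V):\n",
              x$stage, x$f0, x$tone_amplitude))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Stage parameters at a calibrated distortion level
#'
#' Level 0 returns the base (linear) stage: slew limiting disabled for the
#' amplifiers, unperturbed ladder for the ADC.
#'
#' @param cal a [calibrate_levels()] result
#' @param level integer level, 0 .. nrow(cal$table) - 1
#' @param seed ladder seed (ADC only; perturbation is redrawn per seed)
#' @param n_bits ADC resolution override (ADC only)
#' @return `amp_params` or `adc_params`
#' @export
params_at_level <- function(cal, level, seed = 1, n_bits = NULL) {
  stopifnot(inherits(cal, "distortion_levels"))
  row <- cal$table[cal$table$level == level, ]
  if (nrow(row) != 1) stop("unknown level ", level)
  if (cal$stage == "ADC") {
    adc_params(n_bits = if (is.null(n_bits)) cal$base$n_bits else n_bits,
               v_min = cal$base$v_min, v_max = cal$base$v_max,
               perturb_sigma = if (level == 0) 0 else row$knob,
               noise_floor = cal$base$noise_floor, seed = seed)
  } else {
    if (level == 0) return(cal$base)
    amp_at_scale(cal$base, row$knob, cal$sr_gbw_ratio)
  }
}

muffle_alias <- function(expr) {
  withCallingHandlers(expr, spikechain_alias_warning = function(w) {
    invokeRestart("muffleWarning")
  })
}

#' Run a signal through the full LNA-PGA-ADC chain
#'
#' @param x input voltage series (V, electrode scale)
#' @param fs sampling rate (Hz)
#' @param lna,pga [amp_params()] for the two amplifier stages
#' @param adc [adc_params()] for the converter
#' @param seed base seed for the stage noise draws
#' @return chain output voltage series
#' @export
run_chain <- function(x, fs, lna = lna_params(), pga = pga_params(),
                      adc = adc_params(), seed = 0) {
  y <- muffle_alias(process_amplifier(x, fs, lna, seed = seed + 11L))
  y <- muffle_alias(process_amplifier(y, fs, pga, seed = seed + 12L))
  adc_chain(y, fs, adc)
}

#' Reduced benchmark preset
#'
#' 60 s at 24 kHz with 3 units at ~8 Hz total rate: the event density of the
#' emulated annotated benchmark (about 4800 events per 14.4 million samples)
#' at one tenth of its duration, sized for repeated sweeps.
#'
#' @param duration_s record length (s), default 60
#' @param n_units number of units, default 3
#' @param total_rate_hz summed firing rate (Hz), default 8
#' @return list of generator settings for [make_benchmark()]
#' @export
reduced_preset <- function(duration_s = 60, n_units = 3, total_rate_hz = 8) {
  list(duration_s = duration_s, fs = 24000, n_units = n_units,
       rates_hz = rep(total_rate_hz / n_units, n_units),
       noise_sd = 20e-6)
}

#' Full benchmark preset (600 s, ~4800 events)
#' @return generator settings for [make_benchmark()]
#' @export
full_bench_preset <- function() reduced_preset(duration_s = 600)

#' Generate an annotated benchmark recording from a preset
#'
#' @param preset a [reduced_preset()]-style list
#' @param seed integer seed (templates and recording derive sub-seeds)
#' @return an `annotated_recording`
#' @export
make_benchmark <- function(preset = reduced_preset(), seed = 1) {
  tm <- generate_templates(preset$n_units, preset$fs, seed = seed * 7 + 1)
  generate_recording(preset$duration_s, preset$fs, tm, preset$rates_hz,
                     noise_sd = preset$noise_sd, seed = seed * 7 + 2)
}

#' End-to-end detection on a recording through a configured chain
#'
#' Chain output -> 200-3000 Hz band-pass -> median-based 4 sigma threshold
#' -> event detection -> ground-truth matching (1 ms tolerance).
#'
#' @param rec an `annotated_recording`
#' @param lna,pga,adc stage parameters (defaults: linear stages, 12-bit ADC)
#' @param seed chain noise seed
#' @param tol_ms matching tolerance (ms)
#' @return list with `report` (a `detection_report`), `events`, `filtered`,
#'   `threshold`
#' @export
run_detection <- function(rec, lna = lna_params(), pga = pga_params(),
                          adc = adc_params(), seed = 0, tol_ms = 1) {
  stopifnot(inherits(rec, "annotated_recording"))
  y <- run_chain(rec$signal, rec$fs, lna, pga, adc, seed = seed)
  xf <- bandpass(y, rec$fs)
  th <- adaptive_threshold(xf)
  ev <- detect_spikes(xf, rec$fs, th$thr)
  rep <- match_events(ev, rec$truth_index, rec$fs, tol_ms = tol_ms)
  list(report = rep, events = ev, filtered = xf, threshold = th)
}

#' Median detection accuracy of one configuration over seeds
#'
#' Regenerates the benchmark and the chain noise for each seed and reports
#' per-seed accuracy (in percent) plus detected counts; the median over
#' seeds is the headline number used in the sweeps.
#'
#' @param seeds integer vector of seeds
#' @param preset benchmark preset
#' @param lna_fn,pga_fn,adc_fn functions of the seed returning stage
#'   parameters (defaults: linear stages); the ADC ladder is redrawn per
#'   seed through its seed argument
#' @return data.frame with `seed`, `accuracy_pct`, `tp`, `fp`, `fn`,
#'   `n_detected`
#' @export
detection_accuracy <- function(seeds, preset = reduced_preset(),
                               lna_fn = function(s) lna_params(),
                               pga_fn = function(s) pga_params(),
                               adc_fn = function(s) adc_params(seed = s)) {
  rows <- lapply(seeds, function(s) {
    rec <- make_benchmark(preset, seed = s)
    res <- run_detection(rec, lna_fn(s), pga_fn(s), adc_fn(s), seed = s)
    data.frame(seed = s, accuracy_pct = 100 * res$report$accuracy,
               tp = res$report$tp, fp = res$report$fp, fn = res$report$fn,
               n_detected = length(res$events))
  })
  do.call(rbind, rows)
}

#' Sweep distortion levels and scenarios over the benchmark
#'
#' Runs the spike-processing chain for each scenario (which stages are
#' distorted) at each calibrated level, over `n_reps` independent
#' repetitions (benchmark noise, spike times and ADC ladder are redrawn each
#' repetition). Reports detection accuracy and the spike-count error
#' relative to the same repetition's level-0 baseline.
#'
#' @param cal_lna,cal_pga,cal_adc [calibrate_levels()] results per stage
#' @param scenarios subset of `c("LNA", "PGA", "frontend", "ADC", "all")`
#' @param levels integer vector of levels to run (default 0:4)
#' @param n_reps repetitions per cell (default 10)
#' @param preset benchmark preset
#' @param base_seed seeds are derived as
#'   `base_seed + scenario_index * 1000 + rep`
#' @return data.frame with one row per (scenario, level, rep)
#' @export
run_sweep <- function(cal_lna, cal_pga, cal_adc,
                      scenarios = c("LNA", "PGA", "frontend", "ADC", "all"),
                      levels = 0:4, n_reps = 10,
                      preset = reduced_preset(), base_seed = 42) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  out <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    for (rep_i in seq_len(n_reps)) {
      s <- base_seed + si * 1000L + rep_i
      rec <- make_benchmark(preset, seed = s)
      base_count <- NA_integer_
      for (lv in sort(unique(c(0L, levels)))) {
        lna <- if (sc %in% c("LNA", "frontend", "all")) {
          params_at_level(cal_lna, lv)
        } else cal_lna$base
        pga <- if (sc %in% c("PGA", "frontend", "all")) {
          params_at_level(cal_pga, lv)
        } else cal_pga$base
        adc <- if (sc %in% c("ADC", "all")) {
          params_at_level(cal_adc, lv, seed = s + lv)
        } else params_at_level(cal_adc, 0, seed = s)
        res <- run_detection(rec, lna, pga, adc, seed = s + 100L * lv)
        ndet <- length(res$events)
        if (lv == 0L) base_count <- ndet
        if (!(lv %in% levels)) next
        out[[length(out) + 1L]] <- data.frame(
          scenario = sc, level = lv, rep = rep_i, seed = s,
          accuracy_pct = 100 * res$report$accuracy,
          tp = res$report$tp, fp = res$report$fp, fn = res$report$fn,
          n_detected = ndet,
          count_error_pct = spike_count_error(ndet, base_count))
      }
    }
  }
  do.call(rbind, out)
}

#' ADC-resolution sweep with an ideal ladder
#'
#' Detection accuracy over seeds for ideal (unperturbed) ADCs of the given
#' resolutions, front end linear.
#'
#' @param bits vector of resolutions (default 8, 10, 12)
#' @param seeds integer seeds
#' @param preset benchmark preset
#' @return data.frame with `n_bits`, `seed`, `accuracy_pct`
#' @export
resolution_sweep <- function(bits = c(8, 10, 12), seeds = 1:10,
                             preset = reduced_preset()) {
  rows <- lapply(bits, function(b) {
    acc <- detection_accuracy(seeds, preset,
                              adc_fn = function(s) {
                                adc_params(n_bits = b, seed = s)
                              })
    data.frame(n_bits = b, seed = acc$seed, accuracy_pct = acc$accuracy_pct)
  })
  do.call(rbind, rows)
}
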