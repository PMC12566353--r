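test_that("level calibration hits amplifier THD targets and handles edge cases", {
  cal <- calibrate_levels("LNA", targets = c(-40.93), tol_db = 1.5)
  row <- cal$table[cal$table$level == 1, ]
  expect_true(row$met)
  expect_lt(abs(row$achieved_thd_db - (-40.93)), 1.5)
  ## empty target list: only level 0
  cal0 <- calibrate_levels("PGA", targets = numeric(0))
  expect_equal(cal0$table$level, 0)
  ## unreachable target reported unmet with best-found
  bad <- calibrate_levels("LNA", targets = c(-300))
  expect_false(bad$table$met[bad$table$level == 1])
  expect_true(is.finite(bad$table$achieved_thd_db[2]))
  ## level-0 parameters are the linear stage
  p0 <- params_at_level(cal, 0)
  expect_null(p0$SR)
  p1 <- params_at_level(cal, 1)
  expect_false(is.null(p1$SR))
  expect_equal(p1$SR / p1$GBW, cal$sr_gbw_ratio)
})

test_that("median ADC THD responds monotonically over the perturbation search range", {
  fs <- 24000
  f0 <- coherent_tone_freq(fs, fs, 1110)
  tone <- generate_test_tone(f0 = f0, fs = fs, duration = 1,
                             amplitude = 0.999 * 0.6)
  med_thd <- vapply(c(1, 4, 16, 64, 256), function(sig) {
    median(vapply(1:10, function(s) {
      p <- adc_params(perturb_sigma = sig, seed = s)
      tone_metrics(adc_chain(tone$signal, fs, p), fs, f0)$thd_db
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_thd) > 0))
})

test_that("the sweep driver produces complete, well-formed bookkeeping", {
  cal_lna <- get_cal("LNA")
  cal_pga <- get_cal("PGA")
  cal_adc <- get_cal("ADC")
  sw <- run_sweep(cal_lna, cal_pga, cal_adc,
                  scenarios = c("LNA", "ADC"), levels = 0:1, n_reps = 2,
                  preset = reduced_preset(duration_s = 10), base_seed = 7)
  expect_equal(nrow(sw), 2 * 2 * 2)
  expect_true(all(sw$accuracy_pct >= 0 & sw$accuracy_pct <= 100))
  expect_true(all(sw$count_error_pct[sw$level == 0] == 0))
  expect_setequal(unique(sw$scenario), c("LNA", "ADC"))
  ## seeds follow the scenario/repetition derivation
  expect_setequal(unique(sw$seed[sw$scenario == "LNA"]), 7 + 1000 + 1:2)
})

test_that("per-cluster waveform deformation (NRMSE) grows with distortion level", {
  cal_lna <- get_cal("LNA")
  cal_pga <- get_cal("PGA")
  preset <- reduced_preset(duration_s = 20)
  per_seed <- sapply(1:5, function(si) {
    rec <- make_benchmark(preset, seed = si)
    ## cluster mean waveforms per unit, extracted at the annotated times
    cluster_means <- function(lv) {
      y <- run_chain(rec$signal, rec$fs,
                     lna = params_at_level(cal_lna, lv),
                     pga = params_at_level(cal_pga, lv),
                     seed = si + 100 * lv)
      xf <- bandpass(y, rec$fs)
      wm <- extract_align(xf, rec$fs, rec$truth_index, search_ms = 0.25)
      labs <- rec$truth_labels[wm$kept_input]
      t(vapply(1:3, function(u) {
        colMeans(wm$waveforms[labs == u, , drop = FALSE])
      }, numeric(ncol(wm$waveforms))))
    }
    ref <- cluster_means(0)
    vapply(1:4, function(lv) {
      cm <- cluster_means(lv)
      median(vapply(1:3, function(u) nrmse(ref[u, ], cm[u, ]), numeric(1)))
    }, numeric(1))
  })
  med_by_level <- c(0, apply(per_seed, 1, median))
  expect_true(all(diff(med_by_level) > 0))
})

test_that("front-end spike-count error at level 4 exceeds level 1 (median over seeds)", {
  cal_lna <- get_cal("LNA")
  cal_pga <- get_cal("PGA")
  preset <- reduced_preset(duration_s = 30)
  errs <- sapply(1:6, function(si) {
    rec <- make_benchmark(preset, seed = si)
    counts <- vapply(c(0, 1, 4), function(lv) {
      res <- run_detection(rec, lna = params_at_level(cal_lna, lv),
                           pga = params_at_level(cal_pga, lv),
                           seed = si + 10 * lv)
      length(res$events)
    }, numeric(1))
    c(l1 = abs(spike_count_error(counts[2], counts[1])),
      l4 = abs(spike_count_error(counts[3], counts[1])))
  })
  expect_gt(median(errs["l4", ]), median(errs["l1", ]))
})
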