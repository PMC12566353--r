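test_that("templates are AC-coupled, distinct and reproducible", {
  tm <- generate_templates(3, 24000, seed = 1)
  expect_equal(nrow(tm$templates), 3)
  for (u in 1:3) {
    w <- tm$templates[u, ]
    expect_lt(abs(sum(w)) / sum(abs(w)), 0.01)       # near-zero net area
    expect_lt(min(w), 0)                              # negative trough
    expect_gt(max(w), 0)                              # positive overshoot
    expect_gt(abs(min(w)), max(w))                    # trough dominates
  }
  ## pairwise non-proportional shapes
  for (a in 1:2) for (b in (a + 1):3) {
    na_ <- tm$templates[a, ] / sqrt(sum(tm$templates[a, ]^2))
    nb <- tm$templates[b, ] / sqrt(sum(tm$templates[b, ]^2))
    expect_gt(sqrt(sum((na_ - nb)^2)), 0.1)
  }
  tm2 <- generate_templates(3, 24000, seed = 1)
  expect_identical(tm$templates, tm2$templates)
  expect_false(identical(
    tm$templates, generate_templates(3, 24000, seed = 2)$templates))
})

test_that("recordings embed Poisson trains with exact ground truth", {
  fs <- 24000
  tm <- generate_templates(2, fs, seed = 2)
  ## silent units: pure noise, empty truth
  quiet <- generate_recording(2, fs, tm, rates_hz = c(0, 0), seed = 1)
  expect_length(quiet$truth_index, 0)
  expect_equal(length(quiet$signal), 2 * fs)
  ## event count concentrates at duration * total rate
  rec <- generate_recording(100, fs, tm, rates_hz = c(4, 4), seed = 3)
  expected <- 100 * 8
  expect_lt(abs(length(rec$truth_index) - expected), 3 * sqrt(expected))
  expect_true(all(rec$truth_index >= 1 &
                  rec$truth_index <= length(rec$signal)))
  expect_true(all(rec$truth_labels %in% 1:2))
  expect_true(!is.unsorted(rec$truth_index))
  ## within-unit refractory period of 2 ms
  for (u in 1:2) {
    tu <- rec$truth_times[rec$truth_labels == u]
    expect_true(all(diff(tu) >= 2e-3 - 1e-9))
  }
  ## the noiseless part reproduces the template at the annotated position
  clean <- generate_recording(5, fs, tm, rates_hz = c(2, 0), noise_sd = 0,
                              seed = 4)
  i1 <- clean$truth_index[1]
  expect_equal(clean$signal[i1], min(tm$templates[1, ]), tolerance = 1e-9)
})

test_that("the full benchmark preset carries the emulated event density", {
  p <- full_bench_preset()
  expect_equal(p$duration_s * sum(p$rates_hz), 4800)
  expect_equal(p$duration_s * p$fs, 14.4e6)
})

test_that("the test tone is a coherent pure sine at the stated amplitude", {
  tone <- generate_test_tone(f0 = 1110, amplitude = 100e-6, fs = 24000,
                             duration = 1)
  expect_equal(tone$amplitude, 100e-6)
  cycles <- length(tone$signal) * tone$f0 / tone$fs
  expect_equal(cycles %% 1, 0)
  m <- tone_metrics(tone$signal, tone$fs,
                    coherent_tone_freq(24000, length(tone$signal), 1110))
  ## single spectral line: everything but the fundamental is numerically zero
  w <- welch_psd(tone$signal, tone$fs, segment_length = 8000)
  peak <- which.max(w$psd)
  expect_equal(w$freq[peak], 1110, tolerance = 0.01)
  expect_gt(w$psd[peak] / max(w$psd[-seq(peak - 3, peak + 3)]), 1e6)
  ## amplitude recovered from the spectrum
  tone2 <- generate_test_tone(f0 = 1109, fs = 24000, duration = 1)
  m2 <- tone_metrics(tone2$signal, 24000, 1109)
  expect_equal(m2$fundamental_amp, 100e-6, tolerance = 1e-9)
})

test_that("default benchmark units clear the detection threshold with margin", {
  rec <- make_benchmark(reduced_preset(duration_s = 20), seed = 1)
  xf <- bandpass(rec$signal, rec$fs)
  th <- adaptive_threshold(xf)
  troughs <- abs(apply(rec$templates$templates, 1, min))
  ratios <- troughs / th$sigma_n
  expect_true(all(ratios >= 3 & ratios <= 14))
  expect_true(all(troughs * 0.8 > th$thr))  # filtered troughs clear 4 sigma
})
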