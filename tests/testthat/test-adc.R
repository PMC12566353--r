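test_that("the ideal ladder partitions the range at mid-rise thresholds", {
  p <- adc_params(n_bits = 2, v_min = -1, v_max = 1)
  lad <- build_reference_ladder(p)
  expect_equal(lad$thresholds, c(-0.5, 0, 0.5))
  expect_equal(lad$lsb, 0.5)
  expect_equal(quantize(0.75, lad), 3L)
  expect_equal(quantize(-2, lad), 0L)
  expect_equal(quantize(2, lad), 3L)
  expect_equal(codes_to_voltage(0, lad), -1 + 0.25)
})

test_that("perturbed ladders keep 2^n - 1 strictly increasing thresholds at the drawn spread", {
  for (s in 1:5) {
    p <- adc_params(n_bits = 12, perturb_sigma = 0.3, seed = s)
    lad <- build_reference_ladder(p)
    expect_length(lad$thresholds, 2^12 - 1)
    expect_true(all(diff(lad$thresholds) > 0))
  }
  p <- adc_params(n_bits = 12, perturb_sigma = 0.3, seed = 7)
  lad <- build_reference_ladder(p)
  expect_equal(sd((lad$thresholds - lad$ideal) / lad$lsb), 0.3,
               tolerance = 0.1)
})

test_that("quantization is monotone and matches a threshold-count oracle", {
  p <- adc_params(n_bits = 6, perturb_sigma = 0.4, seed = 2)
  lad <- build_reference_ladder(p)
  xs <- seq(p$v_min - 0.1, p$v_max + 0.1, length.out = 1000)
  codes <- quantize(xs, lad)
  expect_true(all(diff(codes) >= 0))
  oracle <- vapply(xs, function(x) sum(lad$thresholds < x), numeric(1))
  expect_equal(codes, as.integer(oracle))
})

test_that("ideal round-trip error is bounded by half an LSB", {
  p <- adc_params(n_bits = 10)
  lad <- build_reference_ladder(p)
  xs <- seq(p$v_min + 1e-9, p$v_max - 1e-9, length.out = 2000)
  err <- abs(codes_to_voltage(quantize(xs, lad), lad) - xs)
  expect_true(all(err <= lad$lsb / 2 + 1e-12))
})

test_that("INL/DNL vanish for the ideal ladder and telescope exactly otherwise", {
  ideal <- build_reference_ladder(adc_params(n_bits = 8))
  ni <- inl_dnl(ideal)
  expect_equal(ni$inl, rep(0, 2^8 - 1))
  expect_equal(ni$dnl, rep(0, 2^8 - 2))
  pert <- build_reference_ladder(adc_params(n_bits = 8, perturb_sigma = 0.4,
                                            seed = 3))
  m <- inl_dnl(pert)
  expect_equal(diff(m$inl), m$dnl, tolerance = 1e-12)
  ## half-LSB threshold scatter typically drives DNL beyond 1 LSB at 12 bits
  maxdnl <- vapply(1:20, function(s) {
    lad <- build_reference_ladder(adc_params(n_bits = 12,
                                             perturb_sigma = 0.5, seed = s))
    max(abs(inl_dnl(lad)$dnl))
  }, numeric(1))
  expect_gt(median(maxdnl), 1)
})

test_that("the ideal chain obeys the quantization-noise SNR law", {
  fs <- 24000
  f0 <- coherent_tone_freq(fs, fs, 1110)
  for (n in c(8, 10, 12)) {
    p <- adc_params(n_bits = n)
    tone <- generate_test_tone(f0 = f0, fs = fs, duration = 1,
                               amplitude = 0.999 * (p$v_max - p$v_min) / 2)
    y <- adc_chain(tone$signal, fs, p)
    snr <- tone_metrics(y, fs, f0)$snr_db
    expect_equal(snr, 6.02 * n + 1.76, tolerance = 0.3 / (6.02 * n + 1.76))
  }
})

test_that("ENOB decreases monotonically with ladder perturbation (median over seeds)", {
  fs <- 24000
  f0 <- coherent_tone_freq(fs, fs, 1110)
  tone <- generate_test_tone(f0 = f0, fs = fs, duration = 1,
                             amplitude = 0.999 * 0.6)
  enob <- vapply(c(0, 5, 20, 80, 300), function(sig) {
    median(vapply(1:10, function(s) {
      p <- adc_params(perturb_sigma = sig, seed = s)
      tone_metrics(adc_chain(tone$signal, fs, p), fs, f0)$enob_bits
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(enob) < 0))
})

test_that("zero input reads back as a constant mid-range code", {
  p <- adc_params()
  y <- adc_chain(numeric(500), 24000, p)
  expect_equal(length(unique(y)), 1L)
  lad <- build_reference_ladder(p)
  expect_lte(abs(y[1]), lad$lsb)
})

test_that("persistent saturation triggers a warning", {
  p <- adc_params(v_min = -0.1, v_max = 0.1)
  expect_warning(adc_chain(rep(0.5, 100), 24000, p), "saturate")
})
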