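test_that("band-pass preserves the spike band and rejects line-frequency drift", {
  fs <- 24000
  t <- (0:(fs - 1)) / fs
  tone1k <- sin(2 * pi * 1000 * t)
  y <- bandpass(tone1k, fs)
  mid <- seq(fs / 4, 3 * fs / 4)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  y50 <- bandpass(sin(2 * pi * 50 * t), fs)
  expect_lt(20 * log10(max(abs(y50[mid]))), -40)
  expect_equal(bandpass(numeric(1000), fs), numeric(1000))
  expect_error(bandpass(tone1k, fs = 5000), "twice")
})

test_that("the median-based threshold estimates Gaussian noise sd", {
  x <- rep(0.6745, 100)
  th <- adaptive_threshold(x)
  expect_equal(th$sigma_n, 1)
  expect_equal(th$thr, 4)
  set.seed(4)
  g <- rnorm(1e6)
  expect_equal(adaptive_threshold(g)$sigma_n, 1, tolerance = 0.01)
  expect_equal(adaptive_threshold(numeric(10))$thr, 0)
})

test_that("the threshold is robust to inserted spikes (median breakdown)", {
  fs <- 24000
  set.seed(5)
  noise <- bandpass(rnorm(10 * fs), fs)
  sig0 <- adaptive_threshold(noise)$sigma_n
  tm <- generate_templates(1, fs, amp_range = c(40, 40), seed = 1)
  spiked <- noise
  starts <- seq(fs / 2, 9.5 * fs, by = fs / 10)  # 10 Hz
  for (s in starts) {
    seg <- s:(s + ncol(tm$templates) - 1)
    spiked[seg] <- spiked[seg] + tm$templates[1, ]
  }
  sig1 <- adaptive_threshold(spiked)$sigma_n
  expect_lt(abs(sig1 - sig0) / sig0, 0.05)
})

test_that("detection finds inserted events and nothing below threshold", {
  fs <- 24000
  set.seed(6)
  noise <- bandpass(rnorm(fs), fs)
  noise <- noise / sd(noise)
  th <- adaptive_threshold(noise)
  tm <- generate_templates(1, fs, amp_range = c(1, 1), seed = 2)
  w <- tm$templates[1, ] / max(abs(tm$templates[1, ])) * 6 * th$sigma_n
  x <- noise
  pos <- 12000
  x[pos:(pos + length(w) - 1)] <- x[pos:(pos + length(w) - 1)] + w
  ev <- detect_spikes(x, fs, th$thr)
  expect_length(ev, 1)
  truth <- pos + which.min(w) - 1
  expect_lt(abs(ev - truth) / fs, 0.5e-3)
  ## everything below threshold: no events
  expect_length(detect_spikes(noise * 0.1, fs, th$thr), 0)
  ## two events separated far beyond the refractory window
  x2 <- noise
  for (p in c(6000, 6000 + 0.02 * fs)) {
    x2[p:(p + length(w) - 1)] <- x2[p:(p + length(w) - 1)] + w
  }
  expect_length(detect_spikes(x2, fs, th$thr), 2)
})

test_that("extraction aligns peaks at the window midpoint and drops clipped windows", {
  fs <- 24000
  x <- numeric(fs)
  tm <- generate_templates(1, fs, amp_range = c(1, 1), seed = 3)
  w <- tm$templates[1, ]
  pos <- 5000
  x[pos:(pos + length(w) - 1)] <- w
  trough <- pos + which.min(w) - 1
  ## report the event a few samples off the true peak: alignment must fix it
  wm <- extract_align(x, fs, events = trough + 4L)
  expect_equal(nrow(wm$waveforms), 1)
  expect_equal(which.max(abs(wm$waveforms[1, ])), wm$peak_index)
  expect_equal(wm$events, trough)
  ## an event at the very start cannot fill a 5 ms window
  wm2 <- extract_align(x, fs, events = c(10L, trough))
  expect_equal(wm2$n_discarded, 1L)
  expect_equal(nrow(wm2$waveforms), 1)
  ## every retained row peaks at the midpoint
  set.seed(7)
  noisy <- x + 0.01 * bandpass(rnorm(fs), fs)
  wm3 <- extract_align(noisy, fs, events = trough)
  expect_true(all(apply(abs(wm3$waveforms), 1, which.max) == wm3$peak_index))
})

test_that("PCA features match a covariance eigendecomposition oracle", {
  set.seed(8)
  base <- matrix(rnorm(2 * 32), 2, 32)
  wf <- base[rep(1:2, each = 10), ] + matrix(rnorm(20 * 32, sd = 1e-3), 20)
  fs_obj <- pca_features(wf, k = 2)
  expect_true(all(diff(fs_obj$explained_var) <= 0))
  ## oracle: eigenvectors of the mean-centered covariance
  cv <- cov(wf)
  eg <- eigen(cv, symmetric = TRUE)
  for (i in 1:2) {
    v <- eg$vectors[, i]
    got <- fs_obj$components[, i]
    expect_lt(min(sum((got - v)^2), sum((got + v)^2)), 1e-8)
    sc_oracle <- as.numeric(wf %*% v)
    d <- min(max(abs(fs_obj$scores[, i] - sc_oracle)),
             max(abs(fs_obj$scores[, i] + sc_oracle)))
    expect_lt(d, 1e-8)
  }
  ## two noiseless templates give exactly two score points
  wf0 <- base[rep(1:2, each = 5), ]
  sc <- pca_features(wf0, k = 2)$scores
  expect_equal(nrow(unique(round(sc, 8))), 2)
  expect_error(pca_features(wf0[1:2, ], k = 2), "more spikes")
})

test_that("k-means sorting separates well-split clusters for any seed", {
  set.seed(9)
  blob <- rbind(matrix(rnorm(40, mean = -10, sd = 0.5), ncol = 2),
                matrix(rnorm(40, mean = 10, sd = 0.5), ncol = 2))
  truth <- rep(1:2, each = 20)
  for (s in c(1, 2, 3, 10, 99)) {
    res <- kmeans_sort(blob, k = 2, seed = s)
    tab <- table(res$labels, truth)
    agreement <- max(sum(diag(tab)), sum(tab[1, 2] + tab[2, 1]))
    expect_equal(agreement, 40)
  }
  ## k = 1: everything in one cluster centered at the mean
  r1 <- kmeans_sort(blob, k = 1, seed = 1)
  expect_true(all(r1$labels == 1))
  expect_equal(as.numeric(r1$centroids), colMeans(blob), tolerance = 1e-9)
  expect_error(kmeans_sort(blob[1:3, ], k = 5), "more clusters")
})

test_that("waveform reassignment corrects score-space confusions and flags outliers", {
  set.seed(10)
  tm <- generate_templates(2, 24000, amp_range = c(1, 1.2), seed = 4)
  wf <- tm$templates[rep(1:2, each = 15), ] +
    matrix(rnorm(30 * ncol(tm$templates), sd = 0.02), 30)
  ## an outlier that scores near cluster 1 (its deviation is orthogonal to
  ## the leading components) but has a deviant waveform shape
  zigzag <- 0.5 * rep_len(c(1, -1), ncol(wf))
  sc30 <- pca_features(wf, k = 2)
  zigzag <- zigzag - sc30$components %*% crossprod(sc30$components, zigzag)
  wf <- rbind(wf, wf[1, ] + as.numeric(zigzag))
  sc <- pca_features(wf, k = 2)
  res <- kmeans_sort(sc, k = 2, seed = 1, waveforms = wf)
  expect_gte(res$n_unclustered, 1)
  expect_equal(res$labels[31], 0L)
  tab <- table(factor(res$labels[1:30], levels = 1:2), rep(1:2, each = 15))
  expect_equal(max(sum(diag(tab)), sum(tab[1, 2] + tab[2, 1])), 30)
})

test_that("event matching reproduces hand-counted scores", {
  r <- match_events(c(101, 350), c(100, 200), fs = 1000, tol_ms = 10)
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 1L)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$accuracy, 1 / 3)
  r2 <- match_events(c(5, 50, 500), c(5, 50, 500), fs = 1000, tol_ms = 1)
  expect_equal(r2$accuracy, 1)
  expect_lte(r$accuracy, min(r$precision, r$recall))
})

test_that("matching equals the exhaustive optimum on random small instances", {
  set.seed(11)
  for (i in 1:50) {
    nd <- sample(0:7, 1)
    nt <- sample(0:7, 1)
    detected <- sort(sample(0:100, nd))
    truth <- sort(sample(0:100, nt))
    tol_samples <- sample(3:15, 1)
    r <- match_events(detected, truth, fs = 1000, tol_ms = tol_samples)
    expect_equal(r$tp, oracle_match_count(detected, truth, tol_samples),
                 info = sprintf("instance %d", i))
  }
  ## an interleaved pattern where greedy nearest-first matching fails
  r <- match_events(c(3, 7), c(0, 4), fs = 1000, tol_ms = 3)
  expect_equal(r$tp, 2L)
})

test_that("spike count error is the signed percentage deviation", {
  expect_equal(spike_count_error(950, 1000), -5)
  expect_equal(spike_count_error(1000, 1000), 0)
  expect_error(spike_count_error(10, 0), "positive")
})
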