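#' Single-tone linearity metrics (SNR, THD, SNDR, SFDR, ENOB)
#'
#' Characterizes a single-tone record from its periodogram. The record is
#' expected to be coherent (an integer number of tone periods, rectangular
#' window); non-coherent records fall back to a 4-term Blackman-Harris window
#' with wider bin clusters around the fundamental and harmonics.
#'
#' Power accounting: the fundamental is the bin cluster at `f0`; harmonic
#' power is collected at k * f0 for k = 2 .. n_harmonics + 1, with harmonics
#' above Nyquist alias-folded back into the first Nyquist zone (standard
#' practice for coherent converter testing); noise is everything else except
#' DC. Then THD = 10 log10(Ph/Pf), SNR = 10 log10(Pf/Pn),
#' SNDR = 10 log10(Pf/(Pn + Ph)), SFDR is fundamental-to-largest-spur and
#' ENOB = (SNDR - 1.76)/6.02.
#'
#' @param x voltage series
#' @param fs sampling rate (Hz)
#' @param f0 tone frequency (Hz); must be resolvable in the record
#' @param n_harmonics number of harmonics counted in THD (default 10)
#' @return object of class `tone_metrics`: list with `snr_db`, `thd_db`,
#'   `sndr_db`, `sfdr_db`, `enob_bits`, `fundamental_amp`, `f0`
#' @examples
#' tone <- generate_test_tone(f0 = 1109, fs = 24000, duration = 1)
#' m <- tone_metrics(tone$signal + 1e-6 * rnorm(length(tone$signal)),
#'                   24000, 1109)
#' m$snr_db
#' @export
tone_metrics <- function(x, fs, f0, n_harmonics = 10) {
  n <- length(x)
  stopifnot(n > 16, fs > 0, f0 > 0, f0 < fs / 2, n_harmonics >= 1)
  cycles <- f0 * n / fs
  if (cycles < 4) stop("tone not resolvable: record shorter than 4 periods")
  coherent <- abs(cycles - round(cycles)) < 1e-6
  if (coherent) {
    w <- rep(1, n)
    halfwidth <- 1L
  } else {
    ## 4-term Blackman-Harris window; 7-bin clusters absorb the leakage
    k <- seq_len(n) - 1L
    w <- 0.35875 - 0.48829 * cos(2 * pi * k / n) +
      0.14128 * cos(4 * pi * k / n) - 0.01168 * cos(6 * pi * k / n)
    halfwidth <- 3L
  }
  X <- fft(x * w)
  nyq <- floor(n / 2)
  p <- Mod(X[seq_len(nyq + 1)])^2  # bins 0 .. Nyquist
  fold_bin <- function(f) {
    fr <- f %% fs
    fr <- ifelse(fr > fs / 2, fs - fr, fr)
    round(fr * n / fs)
  }
  cluster <- function(b) {
    idx <- (b - halfwidth):(b + halfwidth)
    idx <- idx[idx >= 0 & idx <= nyq]
    idx + 1L
  }
  dc_idx <- cluster(0)
  fund_idx <- cluster(fold_bin(f0))
  harm_bins <- vapply(2:(n_harmonics + 1), function(k) fold_bin(k * f0),
                      numeric(1))
  harm_idx <- setdiff(unique(unlist(lapply(harm_bins, cluster))),
                      c(dc_idx, fund_idx))
  p_fund <- sum(p[fund_idx])
  if (p_fund <= 0) stop("no fundamental power at f0; is f0 correct?")
  p_harm <- sum(p[harm_idx])
  p_dc <- sum(p[dc_idx])
  p_noise <- sum(p) - p_fund - p_harm - p_dc
  p_noise <- max(p_noise, .Machine$double.xmin)
  p_harm_safe <- max(p_harm, .Machine$double.xmin)
  ## largest spur: strongest single bin cluster outside DC and fundamental
  spur_p <- 0
  others <- setdiff(seq_len(nyq + 1), c(dc_idx, fund_idx))
  if (length(others)) {
    peak <- others[which.max(p[others])]
    spur_p <- sum(p[cluster(peak - 1L)])
  }
  sndr_db <- 10 * log10(p_fund / (p_noise + p_harm))
  ## amplitude of the fundamental, corrected for the window's coherent gain
  cg <- sum(w) / n
  amp <- 2 * sqrt(p_fund) / (n * cg)
  structure(list(
    snr_db = 10 * log10(p_fund / p_noise),
    thd_db = 10 * log10(p_harm_safe / p_fund),
    sndr_db = sndr_db,
    sfdr_db = 10 * log10(p_fund / max(spur_p, .Machine$double.xmin)),
    enob_bits = (sndr_db - 1.76) / 6.02,
    fundamental_amp = amp,
    f0 = f0), class = "tone_metrics")
}

#' @export
print.tone_metrics <- function(x, ...) {
  cat(sprintf(
    "Tone %.4g Hz: SNR %.2f dB, THD %.2f dB, SNDR %.2f dB, SFDR %.2f dB, ENOB %.2f bits\n",
    x$f0, x$snr_db, x$thd_db, x$sndr_db, x$sfdr_db, x$enob_bits))
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over 50 %-overlapping Hann-windowed
#' segments; one-sided, normalized so that the integral of the PSD over
#' frequency equals the series variance (Parseval).
#'
#' @param x numeric series
#' @param fs sampling rate (Hz)
#' @param segment_length samples per segment (<= length(x))
#' @return list with `freq` (Hz) and `psd` (V^2/Hz)
#' @export
welch_psd <- function(x, fs, segment_length = min(length(x), 4096)) {
  n <- length(x)
  stopifnot(segment_length <= n, segment_length >= 8)
  seg <- as.integer(segment_length)
  step <- max(seg %/% 2, 1L)
  starts <- seq(1L, n - seg + 1L, by = step)
  k <- seq_len(seg) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / (seg - 1))
  u <- sum(w^2)
  nyq <- seg %/% 2
  acc <- numeric(nyq + 1)
  for (s in starts) {
    d <- x[s:(s + seg - 1L)]
    d <- d - mean(d)
    X <- fft(d * w)
    acc <- acc + Mod(X[seq_len(nyq + 1)])^2
  }
  psd <- acc / (length(starts) * u * fs)
  ## one-sided: double interior bins
  if (nyq >= 2) psd[2:nyq] <- 2 * psd[2:nyq]
  list(freq = seq(0, nyq) * fs / seg, psd = psd)
}

#' Normalized root-mean-square error between two waveforms
#'
#' RMS(reference - test) divided by the reference's peak-to-peak range, so
#' deformation is comparable across clusters of different amplitude.
#'
#' @param reference,test equal-length numeric vectors
#' @return non-negative scalar; 0 iff identical
#' @export
nrmse <- function(reference, test) {
  stopifnot(length(reference) == length(test))
  rng <- max(reference) - min(reference)
  if (rng <= 0) stop("flat reference waveform: range is zero")
  sqrt(mean((reference - test)^2)) / rng
}

#' Nearest coherent tone frequency for a record
#'
#' Coherent single-tone testing requires the number of tone cycles in the
#' record to be an integer that is coprime with the record length, so that
#' every sample lands on a distinct tone phase and quantizer error spreads
#' over the spectrum instead of collapsing onto harmonic bins. Returns the
#' frequency M/N * fs with M integer, coprime with N, closest to `f_target`.
#'
#' @param fs sampling rate (Hz)
#' @param n record length (samples)
#' @param f_target desired frequency (Hz)
#' @return frequency in Hz
#' @export
coherent_tone_freq <- function(fs, n, f_target) {
  stopifnot(fs > 0, n > 8, f_target > 0, f_target < fs / 2)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  m0 <- max(round(f_target * n / fs), 1)
  for (d in 0:n) {
    for (m in unique(c(m0 - d, m0 + d))) {
      if (m >= 1 && m < n / 2 && gcd(m, n) == 1) return(m * fs / n)
    }
  }
  stop("no coherent frequency found")  # unreachable for n > 8
}
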