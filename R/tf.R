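#' Continuous-time rational transfer functions
#'
#' Light container for H(s) = num(s)/den(s) with coefficient vectors in
#' ascending powers of s. Used by the amplifier stage models; discretized with
#' the bilinear transform before filtering sampled signals.
#'
#' @param num,den numeric coefficient vectors, ascending powers of s
#' @return an object of class `ctf`
#' @keywords internal
ctf <- function(num, den) {
  stopifnot(is.numeric(num), is.numeric(den), length(den) >= 1L)
  if (all(den == 0)) stop("transfer function denominator is identically zero")
  structure(list(num = as.numeric(num), den = as.numeric(den)), class = "ctf")
}

#' @export
print.ctf <- function(x, ...) {
  fmt <- function(co) paste(signif(co, 4), collapse = ", ")
  cat("Continuous transfer function H(s)\n")
  cat("  num (ascending s):", fmt(x$num), "\n")
  cat("  den (ascending s):", fmt(x$den), "\n")
  invisible(x)
}

poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

poly_eval <- function(co, s) {
  out <- 0 + 0i
  for (k in rev(seq_along(co))) out <- out * s + co[k]
  out
}

#' Evaluate the frequency response of a continuous transfer function
#'
#' @param H a [ctf()] object
#' @param f frequency in Hz (vectorized)
#' @return complex response H(j 2 pi f)
#' @export
tf_response <- function(H, f) {
  stopifnot(inherits(H, "ctf"))
  s <- 2i * pi * f
  vapply(s, function(si) poly_eval(H$num, si) / poly_eval(H$den, si),
         complex(1))
}

#' Magnitude response in dB
#'
#' @inheritParams tf_response
#' @return 20 log10 |H(j 2 pi f)|
#' @export
tf_gain_db <- function(H, f) 20 * log10(Mod(tf_response(H, f)))

#' Discretize a continuous transfer function with the bilinear transform
#'
#' Substitutes s = 2 fs (z - 1)/(z + 1) and expands, yielding digital filter
#' coefficients usable with [signal::filter()]. The bilinear transform
#' preserves stability and low-frequency gain placement, which is what the
#' stage analysis relies on; response near Nyquist is frequency-warped.
#'
#' @param H a [ctf()] object
#' @param fs sampling rate in Hz
#' @return list with `b` (numerator) and `a` (denominator) in descending
#'   powers of z^-1 as expected by [signal::filter()]
#' @export
bilinear_tf <- function(H, fs) {
  stopifnot(inherits(H, "ctf"), fs > 0)
  n <- max(length(H$num), length(H$den))
  num <- c(H$num, numeric(n - length(H$num)))
  den <- c(H$den, numeric(n - length(H$den)))
  ## s^k -> (2 fs)^k (z-1)^k (z+1)^(n-1-k); accumulate polynomials in z
  zm <- c(-1, 1)  # (z - 1), ascending powers of z
  zp <- c(1, 1)   # (z + 1)
  expand <- function(co) {
    out <- numeric(n)
    for (k in seq_len(n) - 1L) {
      if (co[k + 1L] == 0) next
      term <- (2 * fs)^k * co[k + 1L]
      pz <- 1
      if (k > 0) for (i in seq_len(k)) pz <- poly_mul(pz, zm)
      if (n - 1L - k > 0) for (i in seq_len(n - 1L - k)) pz <- poly_mul(pz, zp)
      out <- poly_add(out, term * pz)
    }
    out
  }
  bz <- expand(num)  # ascending powers of z
  az <- expand(den)
  ## convert to descending powers of z (= ascending z^-1) and normalize
  b <- rev(bz)
  a <- rev(az)
  b <- b / a[1]
  a <- a / a[1]
  list(b = b, a = a)
}

#' Filter a sampled signal through a continuous transfer function
#'
#' Discretizes `H` at the working rate via [bilinear_tf()] and applies the
#' resulting IIR filter with zero initial state.
#'
#' @param H a [ctf()] object
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @return filtered signal, same length as `x`
#' @export
apply_tf <- function(H, x, fs) {
  co <- bilinear_tf(H, fs)
  as.numeric(signal::filter(co$b, co$a, x))
}
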