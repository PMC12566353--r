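#' White Gaussian noise with a prescribed one-sided PSD floor
#'
#' Draws a zero-mean Gaussian series whose per-sample variance is
#' `noise_floor * fs / 2`, so that the one-sided power spectral density of the
#' sampled series equals `noise_floor` (flat up to Nyquist). This is the noise
#' primitive used for amplifier input-referred noise and ADC thermal noise.
#'
#' @param n_samples number of samples
#' @param noise_floor one-sided PSD level (V^2/Hz), >= 0
#' @param fs sampling rate (Hz)
#' @param seed integer seed; identical seeds give identical series
#' @return numeric vector of length `n_samples`
#' @examples
#' x <- white_noise(2^14, 1e-16, 24000, seed = 1)
#' var(x)  # ~ 1e-16 * 12000
#' @export
white_noise <- function(n_samples, noise_floor, fs, seed) {
  stopifnot(n_samples > 0, fs > 0, noise_floor >= 0)
  if (noise_floor == 0) return(numeric(n_samples))
  sigma <- sqrt(noise_floor * fs / 2)
  rng <- local_rng(seed)
  rng$rnorm(n_samples, sd = sigma)
}

## Isolated RNG stream: draws from a private .Random.seed so package
## randomness is reproducible under an explicit seed without touching the
## caller's RNG state.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    if (is.null(state)) {
      set.seed(as.integer(seed %% .Machine$integer.max))
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    out <- expr
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    rpois = function(n, lambda) with_state(rpois(n, lambda)),
    rexp = function(n, rate = 1) with_state(stats::rexp(n, rate)),
    sample = function(x, size, replace = FALSE) {
      with_state(sample(x, size, replace = replace))
    }
  )
}
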