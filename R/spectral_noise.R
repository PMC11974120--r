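#' Spectrally shaped (1/f^a) Gaussian noise
#'
#' Generates zero-mean Gaussian noise whose power spectral density falls as
#' `f^-exponent`, by shaping the Fourier amplitudes of white noise. The
#' output is standardized to unit variance (callers scale it to a target
#' RMS). With `exponent = 0` the output is plain white noise.
#'
#' @param length Number of samples (> 0).
#' @param fs Sampling rate in Hz (only sets the physical frequency axis;
#'   the log-log slope is rate-invariant).
#' @param exponent Spectral slope `a` of the `1/f^a` power law.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so that enclosing generators stay reproducible from a single seed).
#' @return Numeric vector of `length` samples, zero mean.
#' @export
#' @examples
#' x <- spectral_noise(2^14, fs = 500, exponent = 1, seed = 1)
#' mean(x)
spectral_noise <- function(length, fs = 500, exponent = 1, seed = NULL) {
  if (length < 1) stop("`length` must be positive")
  gen <- function() {
    n <- length
    if (n == 1) return(stats::rnorm(1))
    w <- stats::rnorm(n)
    if (exponent == 0) {
      x <- w - mean(w)
    } else {
      wf <- stats::fft(w)
      k <- 0:(n - 1)
      k_fold <- pmin(k, n - k)              # two-sided frequency index
      f <- k_fold * fs / n
      scale <- ifelse(f > 0, f^(-exponent / 2), 0)
      x <- Re(stats::fft(wf * scale, inverse = TRUE)) / n
    }
    s <- stats::sd(x)
    if (s > 0) x <- x / s
    x - mean(x)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
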