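# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered discrete Fourier transform
#'
#' Forward transform of a complex time series onto a frequency grid running
#' from -sw/2 to +sw/2 (exclusive), i.e. `fftshift(fft(x))`. The inverse
#' applies the 1/N normalization so that `ift_shifted(ft_shifted(x))`
#' round-trips to machine precision.
#'
#' @param x complex vector.
#' @return complex vector of the same length.
#' @keywords internal
ft_shifted <- function(x) {
  n <- length(x)
  s <- stats::fft(x)
  # move the negative-frequency half to the front
  half <- ceiling(n / 2)
  c(s[(half + 1):n], s[1:half])
}

#' @rdname ft_shifted
#' @keywords internal
ift_shifted <- function(s) {
  n <- length(s)
  half <- ceiling(n / 2)
  unshifted <- c(s[(n - half + 1):n], s[1:(n - half)])
  stats::fft(unshifted, inverse = TRUE) / n
}

#' Frequency axis of the centered transform
#'
#' @param n grid size, sw spectral width in Hz.
#' @return Hz offsets from the carrier, length n, strictly increasing.
#' @keywords internal
shifted_freqs <- function(n, sw) {
  half <- ceiling(n / 2)
  (seq_len(n) - 1 - (n - half)) * sw / n
}

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2^ceiling(log2(n))
}

#' Deterministic substream seed
#'
#' Mixes a master seed with a repetition index and a purpose tag so that each
#' random draw dimension has its own reproducible stream: adding a new
#' randomization never perturbs existing ones. Result stays below 2^31.
#' @keywords internal
substream_seed <- function(seed, rep_index, purpose) {
  h <- (abs(seed) %% 2147483647)
  for (v in c(rep_index, purpose, 17L)) {
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

#' Complex circular Gaussian noise
#'
#' Independent N(0, sigma^2) real and imaginary parts, so the magnitude-wise
#' standard deviation per quadrature channel is `sigma`.
#' @keywords internal
complex_noise <- function(n, sigma) {
  complex(real = stats::rnorm(n, 0, sigma),
          imaginary = stats::rnorm(n, 0, sigma))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
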