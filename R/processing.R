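#' Apodization window specification
#'
#' @param kind `"square_sine"` (sine-squared bell) or `"none"`.
#' @param phase_shift_deg phase shift in degrees, in `[0, 90]`. With a 90
#'   degree shift the window starts at 1 and decreases monotonically to 0 —
#'   the standard choice after model data are inserted, since it de-weights
#'   the calculated tail.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(kind = c("square_sine", "none"), phase_shift_deg = 90) {
  kind <- match.arg(kind)
  stopifnot(phase_shift_deg >= 0, phase_shift_deg <= 90)
  structure(list(kind = kind, phase_shift_deg = phase_shift_deg),
            class = "window_spec")
}

#' Apply an apodization window
#'
#' For the square-sine window the weight at point `k` (0-based, N points) is
#' \deqn{w_k = \sin^2\big(\pi (s + (1-s) k/(N-1))\big), \quad s = \mathrm{shift}/180.}
#' A 90 degree shift gives `s = 0.5`: `w_0 = 1`, `w_{N-1} = 0`, monotonically
#' decreasing.
#'
#' @param x complex vector (length >= 2).
#' @param w a [window_spec()].
#' @export
apply_window <- function(x, w = window_spec()) {
  if (w$kind == "none") return(x)
  n <- length(x)
  stopifnot(n >= 2)
  s <- w$phase_shift_deg / 180
  k <- seq_len(n) - 1
  x * sin(pi * (s + (1 - s) * k / (n - 1)))^2
}

#' Fourier transform an interferogram to a spectrum
#'
#' Standard processing chain: optional first-point scaling (x0.5 when
#' `t0 = 0`, the usual DC-offset convention), apodization, zero-filling to
#' `zero_fill_factor` times the next power of two, centered discrete Fourier
#' transform, and a global zero-order phase. The frequency axis is in Hz
#' with 0 at the carrier.
#'
#' @param fid an [interferogram()] (all points are transformed as given —
#'   run a reconstruction first for truncated data).
#' @param w a [window_spec()].
#' @param zero_fill_factor integer >= 1.
#' @param phase_deg zero-order phase correction in degrees.
#' @param first_point_scale halve the first point before FT (only applied
#'   when the grid starts at t0 = 0).
#' @return an object of class `nmr_spectrum`: list with `freq_hz`, complex
#'   `values`, and a `provenance` record.
#' @export
to_spectrum <- function(fid, w = window_spec(), zero_fill_factor = 4,
                        phase_deg = 0, first_point_scale = TRUE) {
  stopifnot(zero_fill_factor >= 1)
  x <- fid$data
  if (first_point_scale && fid$grid$t0 == 0) x[1] <- x[1] * 0.5
  x <- apply_window(x, w)
  ns <- zero_fill_factor * next_pow2(length(x))
  x <- c(x, complex(real = numeric(ns - length(x))))
  s <- ft_shifted(x) * exp(1i * phase_deg * pi / 180)
  structure(list(freq_hz = shifted_freqs(ns, spectral_width(fid$grid)),
                 values = s,
                 provenance = list(window = w,
                                   zero_fill_factor = zero_fill_factor,
                                   n_points_in = fid$grid$n_points,
                                   phase_deg = phase_deg)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.6g .. %.6g Hz\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}

#' Peak height in a spectrum
#'
#' Returns the maximum of the real part within `search_window_hz/2` of the
#' nominal position (local-maximum convention, robust to small shifts of
#' the true peak off the nominal frequency). With `mode = "nominal"`, or
#' when the window contains no grid point, the real part at the nearest
#' grid point is returned.
#'
#' @param spec an `nmr_spectrum`.
#' @param at_hz nominal peak position in Hz.
#' @param search_window_hz full width of the search window (default 54 Hz,
#'   matching the SIFT bright-region width).
#' @param mode `"local_max"` or `"nominal"`.
#' @return list with `height` and the located `freq_hz`.
#' @export
peak_height <- function(spec, at_hz, search_window_hz = 54,
                        mode = c("local_max", "nominal")) {
  mode <- match.arg(mode)
  f <- spec$freq_hz
  if (at_hz < min(f) || at_hz > max(f)) stop("at_hz outside the spectral range")
  re <- Re(spec$values)
  nearest <- which.min(abs(f - at_hz))
  if (mode == "nominal")
    return(list(height = re[nearest], freq_hz = f[nearest]))
  idx <- which(abs(f - at_hz) <= search_window_hz / 2)
  if (!length(idx)) idx <- nearest
  top <- idx[which.max(re[idx])]
  list(height = re[top], freq_hz = f[top])
}
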