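#' Non-uniform sampling schedule
#'
#' Sorted unique 0-based indices of the sampled points of an indirect
#' dimension (the hmsIST one-index-per-line convention). The first increment
#' (index 0) is always sampled.
#'
#' @param indices integer vector of 0-based sampled indices.
#' @param n_total total number of points of the full grid.
#' @return an object of class `sampling_schedule` with derived `coverage`.
#' @export
sampling_schedule <- function(indices, n_total) {
  indices <- sort(unique(as.integer(indices)))
  stopifnot(n_total >= 1)
  if (length(indices) == 0 || min(indices) < 0 || max(indices) >= n_total)
    stop("schedule indices must lie in [0, n_total)")
  if (indices[1] != 0L)
    stop("schedule must include index 0 (the first increment)")
  structure(list(indices = indices, n_total = as.integer(n_total),
                 coverage = length(indices) / n_total),
            class = "sampling_schedule")
}

#' @rdname sampling_schedule
#' @param schedule a `sampling_schedule`.
#' @export
schedule_to_mask <- function(schedule) {
  mask <- rep(FALSE, schedule$n_total)
  mask[schedule$indices + 1L] <- TRUE
  mask
}

#' Forward linear-prediction coefficients
#'
#' Least-squares autoregressive fit over all complete forward windows:
#' coefficients `c` minimize the residual of
#' `x[k] = sum_i c[i] * x[k-i]` over `k = order+1 .. M`. Roots of the
#' characteristic polynomial with modulus > 1 are reflected inside the unit
#' circle before the coefficients are re-formed, so the recursive extension
#' can never grow.
#'
#' @param recorded complex vector of recorded points (length >= 2*order).
#' @param order number of coefficients (>= 1).
#' @return complex vector of `order` prediction coefficients.
#' @export
lp_coefficients <- function(recorded, order) {
  recorded <- as.complex(recorded)
  m <- length(recorded)
  if (order < 1) stop("LP order must be >= 1")
  if (m < 2 * order)
    stop("need at least 2*order = ", 2 * order, " recorded points, got ", m)
  rows <- (order + 1):m
  a <- t(vapply(rows, function(k) recorded[(k - 1):(k - order)],
                complex(order)))
  if (order == 1) a <- matrix(a, ncol = 1)
  b <- recorded[rows]
  cf <- qr.coef(qr(a, LAPACK = TRUE), b)
  cf[is.na(cf)] <- 0 + 0i
  reflect_roots(cf)
}

# Reflect characteristic-polynomial roots with |z| > 1 to 1/Conj(z).
reflect_roots <- function(cf) {
  p <- length(cf)
  # polynomial z^p - c1 z^(p-1) - ... - cp, coefficients in increasing order
  roots <- polyroot(c(-rev(cf), 1))
  outside <- Mod(roots) > 1
  if (!any(outside)) return(cf)
  roots[outside] <- 1 / Conj(roots[outside])
  # rebuild monic polynomial from roots by convolution
  poly <- 1 + 0i
  for (r in roots) poly <- c(poly, 0i) - c(0i, poly * r)
  # poly = (a_p=1, a_{p-1}, ..., a_0) in decreasing order; c_i = -a_{p-i}
  -poly[-1]
}

#' Linear-prediction extension of a truncated interferogram
#'
#' Conserves the recorded prefix and appends points recursively, each new
#' point being the coefficient-weighted sum of the preceding `order` points.
#' Requires truncated (prefix) sampling.
#'
#' @param fid an [interferogram()] whose mask is a prefix of `TRUE`s.
#' @param order number of LP coefficients.
#' @param target_n_points output length.
#' @export
lp_extend <- function(fid, order, target_n_points) {
  rec <- which(fid$sampled)
  if (!identical(rec, seq_len(length(rec))))
    stop("linear prediction requires truncated (prefix) sampling")
  m <- length(rec)
  if (target_n_points < m) stop("target shorter than recorded prefix")
  cf <- lp_coefficients(fid$data[rec], order)
  x <- c(fid$data[rec], complex(real = numeric(target_n_points - m)))
  p <- length(cf)
  if (target_n_points > m) {
    for (k in (m + 1):target_n_points) {
      x[k] <- sum(cf * x[(k - 1):(k - p)])
    }
  }
  grid_out <- extend_grid(fid$grid, target_n_points)
  mask <- rep(FALSE, target_n_points); mask[rec] <- TRUE
  interferogram(x, grid_out, mask)
}

#' SIFT bright-region support mask
#'
#' Marks the spectral grid points lying within `width_hz/2` of any guide
#' frequency (the "bright regions" where signal is allowed); overlapping
#' regions merge.
#'
#' @param freqs guide frequencies in Hz.
#' @param width_hz full width of each bright region (54 Hz default usage).
#' @param grid_freqs Hz positions of the spectral grid points.
#' @return logical vector over `grid_freqs`.
#' @export
bright_mask <- function(freqs, width_hz, grid_freqs) {
  stopifnot(width_hz > 0)
  if (!length(freqs)) return(rep(FALSE, length(grid_freqs)))
  Reduce(`|`, lapply(freqs, function(f) abs(grid_freqs - f) <= width_hz / 2))
}

#' SIFT reconstruction
#'
#' Spectroscopy with Integration of Frequency and Time domain: alternating
#' projection between the frequency-domain support constraint (zero all
#' spectrum points outside the bright regions) and time-domain data
#' consistency (overwrite recorded points with measured values). Operates on
#' the zero-filled spectral grid defined by `length(mask)`.
#'
#' @param fid an [interferogram()].
#' @param mask logical support mask over the zero-filled spectral grid
#'   (length >= `target_n_points`).
#' @param n_iter number of iterations (default 50).
#' @param target_n_points output interferogram length.
#' @return an [interferogram()] of `target_n_points` points; recorded points
#'   are conserved exactly (the measured-data restoration is the final step).
#' @export
sift_reconstruct <- function(fid, mask, n_iter = 50L,
                             target_n_points = fid$grid$n_points) {
  stopifnot(n_iter >= 1, length(mask) >= target_n_points)
  if (!any(mask))
    message("SIFT support mask is empty; result is equivalent to zero-filling")
  rec <- which(fid$sampled)
  ns <- length(mask)
  x <- complex(real = numeric(ns))
  x[rec] <- fid$data[rec]
  for (i in seq_len(n_iter)) {
    s <- ft_shifted(x)
    s[!mask] <- 0 + 0i
    x <- ift_shifted(s)
    x[rec] <- fid$data[rec]
  }
  grid_out <- extend_grid(fid$grid, target_n_points)
  outmask <- rep(FALSE, target_n_points); outmask[rec] <- TRUE
  interferogram(x[seq_len(target_n_points)], grid_out, outmask)
}

#' Sinusoidal-weighted Poisson-gap sampling schedule
#'
#' Generates a non-uniform sampling schedule in which the gaps between
#' sampled indices are Poisson distributed with a mean that grows toward
#' late evolution times as `sin(theta)^sine_weight` (theta from 0 to pi/2
#' across the grid), so early high-signal points are sampled densely. The
#' gap rate is auto-tuned until exactly `round(coverage * n_total)` indices
#' are produced; the result is deterministic for a fixed seed and always
#' includes index 0.
#'
#' @param n_total full grid length.
#' @param coverage sampling coverage in (0, 1].
#' @param sine_weight weighting exponent (default 2).
#' @param seed integer seed.
#' @return a [sampling_schedule()].
#' @export
poisson_gap_schedule <- function(n_total, coverage, sine_weight = 2, seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1, n_total >= 1)
  k <- round(coverage * n_total)
  if (k >= n_total) return(sampling_schedule(0:(n_total - 1), n_total))
  if (k < 1) stop("coverage too small: no points would be sampled")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  wbar <- mean(sin((seq_len(n_total) - 0.5) / n_total * pi / 2)^sine_weight)
  adj <- (n_total / k - 1) / wbar
  for (attempt in seq_len(20000L)) {
    idx <- integer(0)
    pos <- 0L
    while (pos < n_total && length(idx) < n_total) {
      idx <- c(idx, pos)
      lam <- adj * sin((pos + 0.5) / n_total * pi / 2)^sine_weight
      pos <- pos + 1L + stats::rpois(1L, lam)
    }
    if (length(idx) == k) return(sampling_schedule(idx, n_total))
    # too many indices -> gaps too small -> raise the rate (and vice versa)
    adj <- max(adj * (1 + 0.5 * (length(idx) / k - 1)), 1e-6)
  }
  stop("Poisson-gap rate tuning failed to hit the requested coverage")
}

#' Compressed-sensing reconstruction by iterative soft thresholding
#'
#' hmsIST-style IST: at each iteration the spectrum of the current residual
#' is soft-thresholded at a level that decays linearly from the initial
#' spectrum maximum to zero, the thresholded component is accumulated, and
#' its time-domain image is subtracted from the residual at the sampled
#' points only. Data consistency at the sampled points is re-imposed on the
#' final output.
#'
#' @param fid an [interferogram()] with an arbitrary (NUS) sampling mask.
#' @param n_iter iterations (default 400).
#' @param target_n_points output length.
#' @param zero_fill_factor internal spectral grid = factor x next power of
#'   two of the target length.
#' @return an [interferogram()] of `target_n_points` points with recorded
#'   points conserved.
#' @export
ist_reconstruct <- function(fid, n_iter = 400L,
                            target_n_points = fid$grid$n_points,
                            zero_fill_factor = 1) {
  stopifnot(n_iter >= 1)
  rec <- which(fid$sampled)
  ns <- zero_fill_factor * next_pow2(target_n_points)
  resid <- complex(real = numeric(ns))
  resid[rec] <- fid$data[rec]
  spec_acc <- complex(real = numeric(ns))
  tau0 <- max(Mod(ft_shifted(resid)))
  for (i in seq_len(n_iter)) {
    s <- ft_shifted(resid)
    thr <- tau0 * (1 - i / n_iter)
    mag <- Mod(s)
    shrink <- ifelse(mag > 0, pmax(mag - thr, 0) / mag, 0)
    s_th <- s * shrink
    spec_acc <- spec_acc + s_th
    contrib <- ift_shifted(s_th)
    resid[rec] <- resid[rec] - contrib[rec]
  }
  x <- ift_shifted(spec_acc)
  x[rec] <- fid$data[rec]
  grid_out <- extend_grid(fid$grid, target_n_points)
  outmask <- rep(FALSE, target_n_points); outmask[rec] <- TRUE
  interferogram(x[seq_len(target_n_points)], grid_out, outmask)
}
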