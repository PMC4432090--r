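#' Damped complex exponential basis
#'
#' Builds the design matrix of the harmonic-inversion model: column `j` is
#' the exponentially damped complex sinusoid
#' \deqn{\Phi_{kj} = \exp(i 2\pi \nu_j t_k - R t_k)}
#' evaluated at the observed time points. Frequencies are the chemical-shift
#' offsets (Hz from the carrier) taken from the guide-FID peak list; the
#' decay rate `relax_rate` is a single uniform transverse relaxation rate
#' applied to every signal.
#'
#' @param frequencies numeric vector of Hz offsets; must lie within the
#'   Nyquist range `±spectral_width/2` of `grid`. May be empty.
#' @param relax_rate uniform decay rate R in s^-1 (>= 0).
#' @param grid a [time_grid()].
#' @param observed_indices 1-based indices of the observed rows; defaults to
#'   the full grid. Returned rows are in ascending index order.
#' @return a `signal_basis`: list with `matrix` (complex, one row per observed
#'   index, one column per frequency), `frequencies`, `relax_rate`, `grid`,
#'   `observed_indices`.
#' @details Two frequencies closer than the resolution limit
#'   `1/(2 t_max)` Hz are permitted (Tikhonov regularization keeps the fit
#'   stable) but flagged with a message, since their amplitudes are not
#'   separately identifiable from the data alone.
#' @export
build_basis <- function(frequencies, relax_rate, grid,
                        observed_indices = seq_len(grid$n_points)) {
  stopifnot(inherits(grid, "time_grid"), is_scalar_number(relax_rate),
            relax_rate >= 0)
  frequencies <- as.numeric(frequencies)
  sw <- spectral_width(grid)
  bad <- which(abs(frequencies) > sw / 2 + 1e-9)
  if (length(bad))
    stop(sprintf("frequency %g Hz (peak #%d) outside the Nyquist range +/-%g Hz",
                 frequencies[bad[1]], bad[1], sw / 2))
  observed_indices <- sort(unique(as.integer(observed_indices)))
  if (length(observed_indices) &&
      (min(observed_indices) < 1 || max(observed_indices) > grid$n_points))
    stop("observed_indices outside [1, n_points]")
  if (length(frequencies) >= 2) {
    tmax <- max_evolution_time(grid)
    if (tmax > 0 && min(diff(sort(frequencies))) < 1 / (2 * tmax))
      message("basis contains frequencies closer than 1/(2 t_max) = ",
              signif(1 / (2 * tmax), 3),
              " Hz; amplitudes are only jointly identifiable")
  }
  tk <- grid_times(grid)[observed_indices]
  mat <- if (length(frequencies)) {
    # outer() over times x frequencies, decay applied row-wise
    exp(outer(tk, frequencies, function(t, f) 2i * pi * f * t) - relax_rate * tk)
  } else {
    matrix(complex(0), nrow = length(tk), ncol = 0)
  }
  structure(list(matrix = mat, frequencies = frequencies,
                 relax_rate = relax_rate, grid = grid,
                 observed_indices = observed_indices),
            class = "signal_basis")
}

#' Tikhonov-regularized amplitude estimation
#'
#' Solves for the complex amplitudes `a` minimizing
#' \deqn{\|\Phi a - y\|^2 + \lambda \|a\|^2.}
#' With `lambda_mode = "relative"` (default) the absolute ridge parameter is
#' `lambda = reg_factor * mean(diag(Phi^H Phi))`, which makes the
#' dimensionless factor (default 0.01) invariant to the number of observed
#' points and to the decay envelope. `lambda_mode = "absolute"` applies
#' `reg_factor` as the raw lambda.
#'
#' @param basis a `signal_basis` from [build_basis()].
#' @param observed complex vector, one value per basis row.
#' @param reg_factor dimensionless Tikhonov factor (>= 0); 0 yields the
#'   plain least-squares solution (via complex QR), which errors when the
#'   system is rank deficient.
#' @param lambda_mode `"relative"` or `"absolute"` (see Details).
#' @return an `amplitude_set`: list with `amplitudes` (complex),
#'   `frequencies`, `reg_factor`, `effective_lambda`.
#' @export
solve_amplitudes <- function(basis, observed, reg_factor = 0.01,
                             lambda_mode = c("relative", "absolute")) {
  stopifnot(inherits(basis, "signal_basis"), reg_factor >= 0)
  lambda_mode <- match.arg(lambda_mode)
  phi <- basis$matrix
  observed <- as.complex(observed)
  if (length(observed) != nrow(phi))
    stop("observed length ", length(observed), " does not match basis rows ",
         nrow(phi))
  j <- ncol(phi)
  if (j == 0L)
    return(amplitude_set(complex(0), basis$frequencies, reg_factor, 0))
  if (nrow(phi) == 0L)
    stop("no observed rows: cannot estimate ", j, " amplitudes")
  gram_diag <- Re(colSums(Conj(phi) * phi))
  lambda <- switch(lambda_mode,
                   relative = reg_factor * mean(gram_diag),
                   absolute = reg_factor)
  if (lambda == 0) {
    if (j > nrow(phi))
      stop("more signals (", j, ") than observed points (", nrow(phi),
           ") with no regularization; set reg_factor > 0 (ridge) to stabilize")
    a <- qr.coef(qr(phi, LAPACK = TRUE), observed)
  } else {
    gram <- Conj(t(phi)) %*% phi
    rhs <- Conj(t(phi)) %*% observed
    a <- solve(gram + diag(lambda, j), rhs)[, 1]
  }
  amplitude_set(unname(a), basis$frequencies, reg_factor, lambda)
}

amplitude_set <- function(amplitudes, frequencies, reg_factor, effective_lambda) {
  structure(list(amplitudes = amplitudes, frequencies = frequencies,
                 reg_factor = reg_factor, effective_lambda = effective_lambda),
            class = "amplitude_set")
}

#' Evaluate the fitted signal model at arbitrary time points
#'
#' Computes \eqn{\sum_j a_j \exp(i 2\pi \nu_j t_k - R t_k)} at the requested
#' grid indices; used to insert model-calculated points into the unrecorded
#' region.
#'
#' @param frequencies Hz offsets, one per amplitude.
#' @param relax_rate uniform decay rate in s^-1.
#' @param amplitudes an `amplitude_set` or a plain complex vector.
#' @param grid a [time_grid()] (may be longer than the fitted data).
#' @param indices 1-based indices at which to evaluate; default all.
#' @return complex vector of length `length(indices)`.
#' @export
synthesize <- function(frequencies, relax_rate, amplitudes, grid,
                       indices = seq_len(grid$n_points)) {
  a <- if (inherits(amplitudes, "amplitude_set")) amplitudes$amplitudes
       else as.complex(amplitudes)
  frequencies <- as.numeric(frequencies)
  if (length(a) != length(frequencies))
    stop("amplitudes (", length(a), ") and frequencies (", length(frequencies),
         ") must correspond one-to-one")
  if (!length(frequencies)) return(complex(real = numeric(length(indices))))
  tk <- grid_times(grid)[indices]
  mat <- exp(outer(tk, frequencies, function(t, f) 2i * pi * f * t) -
               relax_rate * tk)
  as.vector(mat %*% a)
}
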