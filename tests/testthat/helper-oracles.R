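# Independent oracles and fixture builders used across the suite.

# Ridge least squares via the real-augmented system: stacks
# [Re(Phi) -Im(Phi); Im(Phi) Re(Phi); sqrt(lambda) I] and solves the real
# problem with qr.solve. Entirely independent of the package's complex
# normal-equations / complex-QR solve path.
ridge_oracle <- function(phi, y, lambda) {
  j <- ncol(phi)
  a_real <- rbind(cbind(Re(phi), -Im(phi)),
                  cbind(Im(phi), Re(phi)))
  b <- c(Re(y), Im(y))
  if (lambda > 0) {
    a_real <- rbind(a_real, sqrt(lambda) * diag(2 * j))
    b <- c(b, numeric(2 * j))
  }
  z <- qr.solve(a_real, b)
  complex(real = z[seq_len(j)], imaginary = z[j + seq_len(j)])
}

# Element-wise brute-force basis evaluation with explicit loops.
basis_oracle <- function(frequencies, relax_rate, grid, observed_indices) {
  tk <- grid_times(grid)[sort(observed_indices)]
  m <- matrix(0 + 0i, length(tk), length(frequencies))
  for (k in seq_along(tk)) for (j in seq_along(frequencies)) {
    m[k, j] <- exp(1i * 2 * pi * frequencies[j] * tk[k] -
                     relax_rate * tk[k])
  }
  m
}

# Closed-form damped exponential at arbitrary times.
continuation_oracle <- function(freq, relax, amp, times) {
  amp * exp(1i * 2 * pi * freq * times - relax * times)
}

# A small random fitting instance (complex design + data).
random_instance <- function(m, j, sw = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- time_grid(m, 1 / sw)
  freqs <- runif(j, -sw / 2 + 10, sw / 2 - 10)
  relax <- runif(1, 0, 30)
  basis <- suppressMessages(build_basis(freqs, relax, grid))
  y <- complex(real = rnorm(m), imaginary = rnorm(m))
  list(basis = basis, y = y, freqs = freqs, relax = relax, grid = grid)
}

# Standard noiseless two-signal truncated fixture on the default grid.
noiseless_fixture <- function(freqs = c(-200, -134), amps = c(2 + 1i, 1 - 0.5i),
                              relax = 23, n = 128, sw = 2000, coverage = 0.25) {
  grid <- time_grid(n, 1 / sw)
  truth <- synthesize(freqs, relax, amps, grid)
  list(truth = truth, grid = grid,
       fid = truncate_fid(interferogram(truth, grid), coverage),
       freqs = freqs, amps = amps, relax = relax)
}
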