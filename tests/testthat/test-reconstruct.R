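test_that("coanafor conserves recorded points bit-identically and continues exactly", {
  fx <- noiseless_fixture(freqs = -200, amps = 2 + 1i, relax = 23)
  cfg <- reconstruction_config(reg_factor = 0, relax_rate = 23,
                               target_n_points = 128)
  out <- coanafor_extend(fx$fid, -200, cfg)
  expect_identical(out$data[1:32], fx$fid$data[1:32])
  expect_lt(max(Mod(out$data - fx$truth)), 1e-8 * max(Mod(fx$truth)))
  expect_identical(which(out$sampled), 1:32)
})

test_that("coanafor with an empty guide list degenerates to zero-filling", {
  fx <- noiseless_fixture()
  cfg <- reconstruction_config(target_n_points = 128)
  out <- coanafor_extend(fx$fid, numeric(0), cfg)
  zf <- zero_fill(fx$fid, 128)
  expect_identical(out$data, zf$data)
})

test_that("coanafor inserted tail equals the independent two-step reimplementation", {
  # compositional oracle: amplitudes from the real-augmented ridge solve,
  # insertion from the closed-form model sum
  fx <- noiseless_fixture(freqs = c(100, 166), amps = c(1 + 0i, 1 + 0i),
                          relax = 20)
  set.seed(42)
  noisy <- fx$fid$data + ifelse(fx$fid$sampled,
                                complex(real = rnorm(128, 0, 0.01),
                                        imaginary = rnorm(128, 0, 0.01)), 0)
  fid <- interferogram(noisy, fx$grid, fx$fid$sampled)
  cfg <- reconstruction_config(reg_factor = 0.01, relax_rate = 20,
                               target_n_points = 128)
  out <- coanafor_extend(fid, c(100, 166), cfg)
  expect_identical(out$data[1:32], fid$data[1:32])

  phi <- basis_oracle(c(100, 166), 20, fx$grid, 1:32)
  lambda <- 0.01 * mean(Re(diag(Conj(t(phi)) %*% phi)))
  a <- ridge_oracle(phi, fid$data[1:32], lambda)
  t_ins <- grid_times(fx$grid)[33:128]
  tail_oracle <- continuation_oracle(100, 20, a[1], t_ins) +
    continuation_oracle(166, 20, a[2], t_ins)
  expect_equal(out$data[33:128], tail_oracle, tolerance = 1e-9)
})

test_that("conservation holds for every method and mask shape", {
  set.seed(7)
  g <- time_grid(64, 1 / 2000)
  masks <- list(prefix = seq_len(64) <= 16,
                nus = {m <- rep(FALSE, 64); m[c(1, sort(sample(2:64, 20)))] <- TRUE; m})
  for (mk in names(masks)) {
    mask <- masks[[mk]]
    data <- complex(real = rnorm(64), imaginary = rnorm(64))
    data[!mask] <- 0
    fid <- interferogram(data, g, mask)
    cfg <- reconstruction_config(target_n_points = 64)
    methods <- if (mk == "prefix") c("coanafor", "zerofill", "lp", "sift", "ist")
               else c("coanafor", "zerofill", "sift", "ist")
    for (m in methods) {
      out <- suppressMessages(reconstruct_1d(fid, c(-300, 200), cfg, m))
      expect_identical(out$data[mask], fid$data[mask],
                       label = sprintf("%s/%s recorded points", m, mk))
    }
  }
})

test_that("anafor equals coanafor on consistent noiseless data, differs under misinformation", {
  fx <- noiseless_fixture(freqs = c(-200, -134), amps = c(1 + 0i, 1 + 0i),
                          relax = 23)
  cfg <- reconstruction_config(reg_factor = 0, anafor_reg_factor = 0,
                               relax_rate = 23, target_n_points = 128)
  an <- anafor_replace(fx$fid, fx$freqs, cfg)
  co <- coanafor_extend(fx$fid, fx$freqs, cfg)
  expect_equal(an$data, co$data, tolerance = 1e-9)
  expect_equal(an$data, fx$truth, tolerance = 1e-8)

  wrong <- fx$freqs + c(0, 3)  # +3 Hz misinformation on signal 2
  an_m <- anafor_replace(fx$fid, wrong, cfg)
  co_m <- coanafor_extend(fx$fid, wrong, cfg)
  expect_identical(co_m$data[1:32], fx$fid$data[1:32])        # still conserved
  expect_gt(max(Mod(an_m$data[1:32] - fx$fid$data[1:32])), 1e-4)  # distorted
})

test_that("anafor refuses rank-deficient fits without regularization", {
  g <- time_grid(16, 1 / 2000)
  fid <- truncate_fid(interferogram(synthesize(0, 10, 1, g), g), 0.25)  # 4 points
  freqs <- seq(-600, 600, length.out = 7)
  cfg <- reconstruction_config(anafor_reg_factor = 0, target_n_points = 16)
  expect_error(anafor_replace(fid, freqs, cfg), "reg_factor")
  cfg$anafor_reg_factor <- 0.01
  expect_s3_class(anafor_replace(fid, freqs, cfg), "interferogram")
})

test_that("regularized solve stays stable on heavily crowded models", {
  set.seed(11)
  g <- time_grid(32, 1 / 2000)
  fid <- interferogram(complex(real = rnorm(32), imaginary = rnorm(32)), g)
  freqs <- runif(64, -900, 900)   # 2x as many signals as points
  cfg <- reconstruction_config(reg_factor = 0.01, target_n_points = 64)
  out <- suppressMessages(coanafor_extend(fid, freqs, cfg))
  expect_true(all(is.finite(Re(out$data)) & is.finite(Im(out$data))))
})

test_that("zero_fill conserves data and zeroes gaps and the extension", {
  g <- time_grid(8, 0.001)
  full <- interferogram(complex(real = 1:8, imaginary = 8:1), g)
  expect_identical(zero_fill(full, 8)$data, full$data)
  ext <- zero_fill(truncate_fid(full, 0.5), 16)
  expect_identical(ext$data[1:4], full$data[1:4])
  expect_identical(ext$data[5:16], rep(0 + 0i, 12))
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  gap <- interferogram(full$data, g, mask)
  zg <- zero_fill(gap, 8)
  expect_identical(zg$data[mask], full$data[mask])
  expect_identical(zg$data[!mask], rep(0 + 0i, 3))
})

test_that("column peak selection uses a closed window and merges duplicates", {
  pk <- guide_peak_list(c("a", "b", "c"), c(-100, 50, 300),
                        direct_ppm = c(8.00, 8.03, 8.05))
  expect_identical(select_signals_for_column(pk, 8.02, 0.02), c(-100, 50))
  expect_identical(select_signals_for_column(pk, 7.00, 0.02), numeric(0))
  # boundary |delta| == window is included
  expect_identical(select_signals_for_column(pk, 8.07, 0.02), 300)
  # merging of unresolvable frequencies
  pk2 <- guide_peak_list(1:3, c(100, 103, 200), direct_ppm = rep(8, 3))
  expect_equal(select_signals_for_column(pk2, 8, 0.02, merge_tol_hz = 5),
               c(101.5, 200))
  expect_error(select_signals_for_column(guide_peak_list("x", 1), 8, 0.02),
               "direct_ppm")
})

test_that("2D reconstruction equals per-column 1D calls and falls back on empty columns", {
  set.seed(3)
  g <- time_grid(64, 1 / 2000)
  n_col <- 8
  direct <- seq(7.9, 8.6, length.out = n_col)
  peaks <- guide_peak_list(c("p", "q"), c(-150, 220),
                           direct_ppm = c(direct[2], direct[5]))
  mat <- matrix(complex(real = rnorm(64 * n_col), imaginary = rnorm(64 * n_col)),
                64, n_col)
  sampled <- seq_len(64) <= 32
  mat[!sampled, ] <- 0
  cfg <- reconstruction_config(target_n_points = 64)
  out <- reconstruct_2d(mat, g, sampled, direct, peaks, cfg, "coanafor")
  expect_identical(dim(out), c(64L, 8L))
  tol <- 1 / (2 * max_evolution_time(g))
  for (j in seq_len(n_col)) {
    fid <- interferogram(mat[, j], g, sampled)
    freqs <- select_signals_for_column(peaks, direct[j], 0.02, tol)
    ref <- if (length(freqs)) coanafor_extend(fid, freqs, cfg)
           else zero_fill(fid, 64)
    expect_identical(out[, j], ref$data)
  }
  # all-empty peak list: whole matrix zero-filled
  empty <- guide_peak_list(character(0), numeric(0), direct_ppm = numeric(0))
  out0 <- reconstruct_2d(mat, g, sampled, direct, empty, cfg, "coanafor")
  expect_identical(out0, {m <- mat; m[!sampled, ] <- 0 + 0i; m})
  expect_error(reconstruct_2d(mat, g, sampled, direct, peaks, cfg, "bogus"),
               "unknown")
})

test_that("target length validation", {
  fx <- noiseless_fixture()
  cfg <- reconstruction_config(target_n_points = 16)
  expect_error(coanafor_extend(fx$fid, -200, cfg), "shorter")
})
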