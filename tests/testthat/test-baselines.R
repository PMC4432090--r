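test_that("LP identifies a single pole and continues multi-exponential data exactly", {
  g <- time_grid(32, 1 / 1000)
  z <- exp(2i * pi * 120 / 1000 - 15 / 1000)   # one decaying pole
  x <- z^(0:31)
  cf <- lp_coefficients(x, 1)
  expect_equal(cf, z, tolerance = 1e-10)

  # two damped exponentials, order 2: forward prediction exact over 32 points
  full <- time_grid(64, 1 / 1000)
  truth <- continuation_oracle(90, 12, 1 + 1i, grid_times(full)) +
    continuation_oracle(-210, 20, 2 - 0.5i, grid_times(full))
  fid <- interferogram(truth, full)
  fid <- truncate_fid(fid, 0.5)
  out <- lp_extend(fid, 2, 64)
  expect_identical(out$data[1:32], truth[1:32])
  expect_lt(max(Mod(out$data[33:64] - truth[33:64])), 1e-8)
})

test_that("LP input validation and coefficient count", {
  set.seed(1)
  x <- complex(real = rnorm(96), imaginary = rnorm(96))
  expect_length(lp_coefficients(x, 16), 16)
  expect_error(lp_coefficients(x[1:20], 16), "2\\*order")
  expect_error(lp_coefficients(x, 0), "order")
  g <- time_grid(8, 1)
  nusfid <- interferogram(complex(real = 1:8), g,
                          c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 4)))
  expect_error(lp_extend(nusfid, 1, 8), "prefix")
})

test_that("root reflection keeps noise extensions bounded", {
  g <- time_grid(128, 1 / 2000)
  for (s in 1:8) {
    set.seed(300 + s)
    x <- complex(real = rnorm(64), imaginary = rnorm(64))
    fid <- interferogram(c(x, rep(0 + 0i, 64)), g,
                         rep(c(TRUE, FALSE), each = 64))
    ext <- lp_extend(fid, 16, 128)$data[65:128]
    expect_lte(max(Mod(ext)), 1.05 * max(Mod(x)))
    cf <- lp_coefficients(x, 16)
    expect_true(all(Mod(polyroot(c(-rev(cf), 1))) <= 1 + 1e-8))
  }
})

test_that("bright mask is the union of closed intervals around the peaks", {
  gf <- seq(-500, 490, by = 10)
  expect_false(any(bright_mask(numeric(0), 54, gf)))
  one <- bright_mask(0, 54, gf)
  expect_identical(which(one), which(abs(gf) <= 27))
  expect_identical(sum(one), 5L)   # -20..20 at 10 Hz spacing
  # 66 Hz apart with 54 Hz widths: two disjoint regions
  two <- bright_mask(c(0, 66), 54, gf)
  r <- rle(two)
  expect_identical(sum(r$values), 2L)
})

test_that("SIFT conserves data, is an identity at full coverage, and converges in-support", {
  g <- time_grid(64, 1 / 2000)
  f0 <- 2000 / 64 * 6
  truth <- synthesize(f0, 0, 1 + 0i, g)
  mask <- bright_mask(f0, 54, coanafor:::shifted_freqs(64, 2000))
  expect_identical(sum(mask), 1L)  # the peak bin alone is bright

  full <- interferogram(truth, g)
  out_full <- sift_reconstruct(full, mask, 10, 64)
  expect_identical(out_full$data, truth)

  fid <- truncate_fid(full, 0.25)
  resid <- vapply(1:50, function(k)
    sqrt(sum(Mod(sift_reconstruct(fid, mask, k, 64)$data - truth)^2)),
    numeric(1))
  expect_true(all(diff(resid) <= 1e-12))      # monotone decrease
  expect_gt(resid[1] / resid[50], 10)

  expect_message(sift_reconstruct(fid, rep(FALSE, 64), 3, 64), "empty")
})

test_that("Poisson-gap schedules hit the coverage exactly and are reproducible", {
  expect_identical(poisson_gap_schedule(32, 1, 2, 1)$indices, 0:31)
  for (cv in c(0.1, 0.25, 0.5)) for (s in c(1, 9)) {
    sch <- poisson_gap_schedule(128, cv, 2, s)
    expect_identical(length(sch$indices), as.integer(round(cv * 128)))
    expect_identical(sch$indices[1], 0L)
    expect_identical(sch$indices, poisson_gap_schedule(128, cv, 2, s)$indices)
  }
  expect_false(identical(poisson_gap_schedule(128, 0.25, 2, 1)$indices,
                         poisson_gap_schedule(128, 0.25, 2, 2)$indices))
})

test_that("sinusoidal weighting samples early evolution times more densely", {
  early <- 0; late <- 0
  for (s in 1:200) {
    idx <- poisson_gap_schedule(128, 0.25, 2, s)$indices
    early <- early + sum(idx < 64)
    late <- late + sum(idx >= 64)
  }
  expect_gt(early, 1.3 * late)
})

test_that("IST conserves sampled points and recovers a sparse spectrum", {
  g <- time_grid(128, 1 / 2000)
  # fully sampled: identity
  set.seed(17)
  x <- complex(real = rnorm(128), imaginary = rnorm(128))
  full <- interferogram(x, g)
  expect_identical(ist_reconstruct(full, 5, 128, 1)$data, x)

  # 1-sparse noiseless spectrum at 50 % Poisson-gap NUS
  f0 <- 2000 / 128 * 10
  truth <- synthesize(f0, 0, 1 + 0i, g)
  sch <- poisson_gap_schedule(128, 0.5, 2, 3)
  m <- schedule_to_mask(sch)
  nus <- interferogram(ifelse(m, truth, 0 + 0i), g, m)
  out <- ist_reconstruct(nus, 400, 128, 1)
  expect_identical(out$data[m], truth[m])   # final data consistency
  sp_out <- to_spectrum(out, window_spec("none"), 1, first_point_scale = FALSE)
  sp_true <- to_spectrum(interferogram(truth, g), window_spec("none"), 1,
                         first_point_scale = FALSE)
  p_out <- peak_height(sp_out, f0, 20)
  p_true <- peak_height(sp_true, f0, 20)
  expect_identical(p_out$freq_hz, p_true$freq_hz)
  expect_lt(abs(p_out$height - p_true$height) / p_true$height, 0.01)
})
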