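#' Peak-height ratio of two spectra
#'
#' The accuracy readout of the simulation studies: the height of signal 1
#' in the data-2 spectrum divided by its height in the data-1 spectrum
#' (`h_ii / h_i`). A non-positive `h_i` makes the ratio meaningless and is
#' flagged by returning `NA` (the caller counts such repetitions).
#'
#' @param spec1,spec2 `nmr_spectrum` objects on the same grid (data 1 and
#'   data 2).
#' @param signal1_hz nominal position of signal 1.
#' @param search_window_hz,mode passed to [peak_height()].
#' @return a single ratio, `NA_real_` if invalid.
#' @export
height_ratio <- function(spec1, spec2, signal1_hz, search_window_hz = 54,
                         mode = "local_max") {
  h_i <- peak_height(spec1, signal1_hz, search_window_hz, mode)$height
  h_ii <- peak_height(spec2, signal1_hz, search_window_hz, mode)$height
  if (!is.finite(h_i) || h_i <= 0) return(NA_real_)
  h_ii / h_i
}

#' Root-mean-square deviation of height ratios
#'
#' `sqrt(mean((ratio - reference)^2))` over repetitions — the RMS deviation
#' of reconstructed peak-height ratios from the reference ratio of fully
#' sampled, unreconstructed data.
#'
#' @param ratios numeric vector of per-repetition ratios (`NA`s removed).
#' @param reference the reference ratio.
#' @export
rmsdelta <- function(ratios, reference) {
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) return(NA_real_)
  sqrt(mean((ratios - reference)^2))
}

# One repetition of the generate -> reconstruct -> measure pipeline.
# Returns the height ratio. `misinfo_methods` get the signal-2 guide entry
# offset by the misinformation draw.
eval_one_rep <- function(scenario, rep_index, method, cfg,
                         misinfo_methods = c("anafor", "sift")) {
  pair <- make_pair(scenario, rep_index)
  freqs <- pair$guide$indirect_hz
  if (method %in% misinfo_methods)
    freqs[match("signal2", pair$guide$id)] <-
      freqs[match("signal2", pair$guide$id)] + pair$draws$misinfo2_hz
  cfg$target_n_points <- scenario$n_points
  # crowded draws routinely place additional signals near each other; the
  # near-duplicate-frequency diagnostics are expected, so keep sweeps quiet
  r1 <- suppressMessages(reconstruct_1d(pair$data1, freqs, cfg, method))
  r2 <- suppressMessages(reconstruct_1d(pair$data2, freqs, cfg, method))
  s1 <- to_spectrum(r1, cfg$window, cfg$zero_fill_factor,
                    first_point_scale = cfg$first_point_scale)
  s2 <- to_spectrum(r2, cfg$window, cfg$zero_fill_factor,
                    first_point_scale = cfg$first_point_scale)
  height_ratio(s1, s2, scenario$signal1_hz, cfg$peak_search_hz, cfg$peak_mode)
}

# Reference ratio: full-coverage, unreconstructed repetitions on their own
# substreams (rep indices offset so they are independent of the sweep reps).
.REF_OFFSET <- 500000L

reference_ratio <- function(scenario, n_reps, cfg) {
  sc <- scenario
  sc$coverage <- 1
  ratios <- vapply(seq_len(n_reps), function(r)
    eval_one_rep(sc, .REF_OFFSET + r, "none", cfg), numeric(1))
  list(reference = mean(ratios, na.rm = TRUE), ratios = ratios)
}

#' Sampling-coverage sweep of reconstruction accuracy
#'
#' For each (method, coverage) cell: generate `n_reps` data-1/data-2 pairs
#' with coverage-scaled noise, reconstruct both to the full length, apodize
#' and Fourier transform, measure the signal-1 height ratio, and aggregate
#' the RMS deviation from the reference ratio. The reference is computed
#' once from `n_reps` full-coverage unreconstructed repetitions on
#' independent noise substreams.
#'
#' @param scenario a [synthetic_scenario()].
#' @param methods character vector of method names ([reconstruct_1d()]).
#' @param coverages numeric vector of coverages in (0, 1].
#' @param n_reps repetitions per cell (>= 2).
#' @param seed master seed (overrides `scenario$seed`).
#' @param cfg a [reconstruction_config()].
#' @param misinfo_methods methods whose signal-2 guide frequency receives
#'   the chemical-shift misinformation draw.
#' @return list with `table` (data.frame: method, coverage, rmsdelta,
#'   n_reps, n_invalid, reference_ratio), `ratios` (per-cell vectors, keyed
#'   `"method@coverage"`), and `reference`.
#' @export
run_coverage_sweep <- function(scenario, methods, coverages, n_reps = 200L,
                               seed = scenario$seed,
                               cfg = reconstruction_config(),
                               misinfo_methods = c("anafor", "sift")) {
  stopifnot(n_reps >= 2)
  scenario$seed <- seed
  ref <- reference_ratio(scenario, n_reps, cfg)
  rows <- list(); ratios <- list()
  for (m in methods) for (cv in coverages) {
    sc <- scenario; sc$coverage <- cv
    rr <- vapply(seq_len(n_reps), function(r)
      eval_one_rep(sc, r, m, cfg, misinfo_methods), numeric(1))
    key <- sprintf("%s@%g", m, cv)
    ratios[[key]] <- rr
    rows[[key]] <- data.frame(method = m, coverage = cv,
                              rmsdelta = rmsdelta(rr, ref$reference),
                              n_reps = n_reps, n_invalid = sum(!is.finite(rr)),
                              reference_ratio = ref$reference)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ratios = ratios, reference = ref)
}

#' Spectral-crowding sweep of reconstruction accuracy
#'
#' As [run_coverage_sweep()], but the sampling coverage is fixed (default
#' 25 %) and the number of additional signals varies. Each crowding level
#' uses its own reference computed from full-coverage unreconstructed data
#' with the same additional signals.
#'
#' @inheritParams run_coverage_sweep
#' @param n_additional_list integer vector of additional-signal counts.
#' @param coverage fixed sampling coverage (default 0.25).
#' @return as [run_coverage_sweep()], with an `n_additional` column.
#' @export
run_crowding_sweep <- function(scenario, methods, n_additional_list,
                               n_reps = 200L, seed = scenario$seed,
                               coverage = 0.25,
                               cfg = reconstruction_config(),
                               misinfo_methods = c("anafor", "sift")) {
  stopifnot(n_reps >= 2)
  scenario$seed <- seed
  rows <- list(); ratios <- list(); refs <- list()
  for (na in n_additional_list) {
    sc0 <- scenario; sc0$n_additional <- as.integer(na)
    ref <- reference_ratio(sc0, n_reps, cfg)
    refs[[as.character(na)]] <- ref$reference
    for (m in methods) {
      sc <- sc0; sc$coverage <- coverage
      rr <- vapply(seq_len(n_reps), function(r)
        eval_one_rep(sc, r, m, cfg, misinfo_methods), numeric(1))
      key <- sprintf("%s@%d", m, as.integer(na))
      ratios[[key]] <- rr
      rows[[key]] <- data.frame(method = m, n_additional = as.integer(na),
                                coverage = coverage,
                                rmsdelta = rmsdelta(rr, ref$reference),
                                n_reps = n_reps,
                                n_invalid = sum(!is.finite(rr)),
                                reference_ratio = ref$reference)
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ratios = ratios, references = refs)
}

#' Slope of RMS-delta versus crowding, with a bootstrap standard error
#'
#' Fits a least-squares line to the per-cell RMS-delta values of one method
#' against the number of additional signals, and bootstraps the repetitions
#' within each cell to attach a standard error to the slope. Used to test
#' whether a method's accuracy degrades with crowding (positive slope beyond
#' noise) or is crowding-independent (slope within noise of zero).
#'
#' @param sweep result of [run_crowding_sweep()].
#' @param method method name present in the sweep.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed seed for the resampling.
#' @return list with `slope`, `se`, and the per-cell `rmsdelta` values.
#' @export
rmsdelta_slope <- function(sweep, method, n_boot = 200L, seed = 1L) {
  tab <- sweep$table[sweep$table$method == method, ]
  x <- tab$n_additional
  y <- tab$rmsdelta
  slope_of <- function(yy) stats::coef(stats::lm(yy ~ x))[[2]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    yb <- vapply(seq_len(nrow(tab)), function(i) {
      key <- sprintf("%s@%d", method, tab$n_additional[i])
      rr <- sweep$ratios[[key]]
      rr <- rr[is.finite(rr)]
      rmsdelta(sample(rr, length(rr), replace = TRUE), tab$reference_ratio[i])
    }, numeric(1))
    slope_of(yb)
  }, numeric(1))
  list(slope = slope_of(y), se = stats::sd(boots), rmsdelta = y)
}
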