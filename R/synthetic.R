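#' Synthetic HSQC-like interferogram scenario
#'
#' Parameters of the two-dataset simulation used throughout the evaluation.
#' Data 1 holds two signals separated by `signal2_sep_hz` (66 Hz); data 2 is
#' identical except that the volume of signal 2 is exactly zero. Per
#' repetition, the chemical shift of signal 2 is re-drawn within
#' `shift2_range_hz` (to randomize how its truncation wiggles interfere with
#' signal 1), a global phase within `phase_range_deg` is applied to both
#' datasets, and a chemical-shift misinformation for signal 2's guide entry
#' is drawn within `misinfo_range_hz`. The time-domain noise level scales as
#' `base_noise_sigma * sqrt(coverage)`, emulating truncated acquisition with
#' proportionally more scans per increment.
#'
#' Unstated constants are fixed at documented, field-plausible defaults: a
#' 2000 Hz spectral width over 128 complex points, signal 1 at -200 Hz from
#' the carrier, equal unit volumes, a transverse relaxation rate decaying
#' the envelope to about exp(-1.5) at the maximum evolution time, and a
#' time-domain signal-to-noise ratio of 50 at full coverage.
#'
#' @param ... override any default field (see the function body for the
#'   complete list).
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(...) {
  sc <- list(
    n_points = 128L,
    sw_hz = 2000,
    signal1_hz = -200,
    signal1_volume = 1,
    signal2_sep_hz = 66,
    signal2_volume = 1,
    relax_rate = NULL,          # default: 1.5 / t_max, filled below
    n_additional = 0L,
    additional_volume = 1,
    base_noise_sigma = 1 / 50,  # time-domain S/N 50 at 100 % coverage
    coverage = 1,
    shift2_range_hz = 15,
    phase_range_deg = 7.5,
    misinfo_range_hz = 3,
    guard_hz = 33,              # keep additional signals off signal 1
    band_margin_hz = 100,       # keep additional signals inside the sweep width
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown)) stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  sc[names(dots)] <- dots
  if (is.null(sc$relax_rate)) {
    tmax <- (sc$n_points - 1) / sc$sw_hz
    sc$relax_rate <- 1.5 / tmax
  }
  stopifnot(sc$n_points >= 4, sc$sw_hz > 0, sc$coverage > 0, sc$coverage <= 1,
            sc$base_noise_sigma >= 0, sc$n_additional >= 0)
  structure(sc, class = "synthetic_scenario")
}

#' Coverage-dependent noise level
#'
#' Truncated acquisition spends the saved time on more scans per increment,
#' so the signal-to-noise ratio of the recorded points improves as the
#' coverage drops: `sigma = base_sigma * sqrt(coverage)`.
#'
#' @param base_sigma noise sigma at 100 % coverage.
#' @param coverage sampling coverage in (0, 1].
#' @export
scale_noise <- function(base_sigma, coverage) {
  stopifnot(coverage > 0, coverage <= 1, base_sigma >= 0)
  base_sigma * sqrt(coverage)
}

# purpose tags for the per-repetition random substreams
.PURPOSE <- c(shift2 = 1L, phase = 2L, misinfo = 3L, positions = 4L,
              noise1 = 5L, noise2 = 6L)

draw_with <- function(seed, rep_index, purpose, fun) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, rep_index, .PURPOSE[[purpose]]))
  fun()
}

#' Generate one data-1 / data-2 repetition
#'
#' Draws the per-repetition randomizations, builds the two noiseless
#' interferograms, applies the global phase, adds independent noise
#' realizations (same sigma) to both, truncates to the scenario coverage,
#' and assembles the guide peak list holding the *true* signal positions.
#' The signal-2 misinformation offset is returned in `draws` and applied by
#' the evaluation layer only for the configured methods.
#'
#' Identical `(seed, rep_index)` give bitwise-identical output; each random
#' dimension has its own substream.
#'
#' @param scenario a [synthetic_scenario()].
#' @param rep_index repetition index (>= 1).
#' @return list with `data1`, `data2` ([interferogram()]s), `draws` (list:
#'   `shift2_offset_hz`, `phase_deg`, `misinfo2_hz`, `additional_hz`),
#'   `guide` (a [guide_peak_list()]), and `noise_sigma`.
#' @export
make_pair <- function(scenario, rep_index = 1L) {
  sc <- scenario
  n <- sc$n_points
  grid <- time_grid(n, 1 / sc$sw_hz)
  t <- grid_times(grid)

  shift2 <- draw_with(sc$seed, rep_index, "shift2",
                      function() stats::runif(1, -sc$shift2_range_hz, sc$shift2_range_hz))
  phase <- draw_with(sc$seed, rep_index, "phase",
                     function() stats::runif(1, -sc$phase_range_deg, sc$phase_range_deg))
  misinfo2 <- draw_with(sc$seed, rep_index, "misinfo",
                        function() stats::runif(1, -sc$misinfo_range_hz, sc$misinfo_range_hz))
  addl <- if (sc$n_additional > 0) {
    draw_with(sc$seed, rep_index, "positions", function() {
      lo <- -sc$sw_hz / 2 + sc$band_margin_hz
      hi <- sc$sw_hz / 2 - sc$band_margin_hz
      out <- numeric(0)
      while (length(out) < sc$n_additional) {
        p <- stats::runif(1, lo, hi)
        if (abs(p - sc$signal1_hz) > sc$guard_hz) out <- c(out, p)
      }
      out
    })
  } else numeric(0)

  s2 <- sc$signal1_hz + sc$signal2_sep_hz + shift2
  model <- function(freqs, vols) {
    if (!length(freqs)) return(complex(real = numeric(n)))
    synthesize(freqs, sc$relax_rate, as.complex(vols), grid)
  }
  clean1 <- model(c(sc$signal1_hz, s2, addl),
                  c(sc$signal1_volume, sc$signal2_volume,
                    rep(sc$additional_volume, length(addl))))
  clean2 <- model(c(sc$signal1_hz, addl),
                  c(sc$signal1_volume, rep(sc$additional_volume, length(addl))))
  rot <- exp(1i * phase * pi / 180)
  sigma <- scale_noise(sc$base_noise_sigma, sc$coverage)
  noise1 <- draw_with(sc$seed, rep_index, "noise1", function() complex_noise(n, sigma))
  noise2 <- draw_with(sc$seed, rep_index, "noise2", function() complex_noise(n, sigma))

  d1 <- interferogram(clean1 * rot + noise1, grid)
  d2 <- interferogram(clean2 * rot + noise2, grid)
  if (sc$coverage < 1) {
    d1 <- truncate_fid(d1, sc$coverage)
    d2 <- truncate_fid(d2, sc$coverage)
  }
  ids <- c("signal1", "signal2",
           if (length(addl)) sprintf("add%02d", seq_along(addl)))
  guide <- guide_peak_list(ids, c(sc$signal1_hz, s2, addl))
  list(data1 = d1, data2 = d2,
       draws = list(shift2_offset_hz = shift2, phase_deg = phase,
                    misinfo2_hz = misinfo2, additional_hz = addl),
       guide = guide, noise_sigma = sigma)
}

#' @rdname make_pair
#' @details `make_crowded()` is [make_pair()] restricted to scenarios with
#'   at least one additional signal (the crowding study); additional signals
#'   are present identically in both datasets, placed uniformly at random in
#'   the usable band outside a `guard_hz` exclusion zone around signal 1.
#' @export
make_crowded <- function(scenario, rep_index = 1L) {
  if (scenario$n_additional < 1)
    stop("make_crowded requires a scenario with n_additional >= 1")
  make_pair(scenario, rep_index)
}
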