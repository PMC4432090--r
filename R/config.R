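#' Reconstruction configuration
#'
#' Collects every tunable of the reconstruction and processing chain with
#' the documented defaults. Field-by-field:
#'
#' * `reg_factor` — dimensionless Tikhonov factor for Co-ANAFOR (0.01).
#' * `anafor_reg_factor` — factor for plain ANAFOR; 0 mirrors the original
#'   unregularized method.
#' * `lambda_mode` — `"relative"` scales the factor by the mean Gram
#'   diagonal (see [solve_amplitudes()]); `"absolute"` uses it raw.
#' * `direct_linewidth_ppm` — half-width of the direct-dimension window used
#'   to pick guide peaks for a column (0.02 ppm, closed interval each side).
#' * `relax_rate` — `"auto"` sets R to the reciprocal of the maximum
#'   evolution time after insertion; or a fixed value in s^-1.
#' * `target_n_points` — length after insertion; `NULL` keeps the grid length.
#' * `window` — a [window_spec()] (square-sine, 90 degree shift).
#' * `zero_fill_factor` — spectrum size = factor x next power of two (4;
#'   interpolates the spectral grid for peak picking).
#' * `first_point_scale` — halve the first time point before FT when t0 = 0.
#' * `bright_width_hz` — full width of each SIFT bright region (54 Hz).
#' * `sift_iter`, `ist_iter` — iteration counts (50 and 400).
#' * `lp_order` — number of linear-prediction coefficients (16).
#' * `peak_search_hz` — full width of the peak-height search window (54 Hz).
#' * `peak_mode` — `"local_max"` measures the maximum of the real part in the
#'   search window; `"nominal"` reads the value at the nominal position.
#'
#' @param ... override any of the fields above.
#' @return an object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(...) {
  cfg <- list(
    reg_factor = 0.01,
    anafor_reg_factor = 0,
    lambda_mode = "relative",
    direct_linewidth_ppm = 0.02,
    relax_rate = "auto",
    target_n_points = NULL,
    window = window_spec("square_sine", 90),
    zero_fill_factor = 4,
    first_point_scale = TRUE,
    bright_width_hz = 54,
    sift_iter = 50L,
    ist_iter = 400L,
    lp_order = 16L,
    peak_search_hz = 54,
    peak_mode = "local_max"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$reg_factor >= 0, cfg$anafor_reg_factor >= 0,
            cfg$direct_linewidth_ppm > 0, cfg$zero_fill_factor >= 1,
            cfg$bright_width_hz > 0, cfg$sift_iter >= 1, cfg$ist_iter >= 1,
            cfg$lp_order >= 1)
  structure(cfg, class = "reconstruction_config")
}

# Resolve the uniform relaxation rate against the post-insertion grid.
resolve_relax_rate <- function(cfg, grid_out) {
  if (identical(cfg$relax_rate, "auto")) 1 / max_evolution_time(grid_out)
  else {
    stopifnot(is_scalar_number(cfg$relax_rate), cfg$relax_rate >= 0)
    cfg$relax_rate
  }
}

resolve_target <- function(cfg, fid) {
  if (!any(fid$sampled))
    stop("interferogram has no recorded points to reconstruct from")
  n <- cfg$target_n_points %||% fid$grid$n_points
  if (n < sum(fid$sampled))
    stop("target_n_points (", n, ") shorter than the number of recorded points (",
         sum(fid$sampled), ")")
  if (n < fid$grid$n_points && any(fid$sampled[(n + 1):fid$grid$n_points]))
    stop("target_n_points would drop recorded points")
  as.integer(n)
}

#' @export
print.reconstruction_config <- function(x, ...) {
  cat("<reconstruction_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (inherits(v, "window_spec"))
      v <- sprintf("%s (%g deg shift)", v$kind, v$phase_shift_deg)
    cat(sprintf("  %-22s %s\n", nm, paste(format(v %||% "NULL"), collapse = " ")))
  }
  invisible(x)
}
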