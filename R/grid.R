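#' Evolution-time grid of an interferogram
#'
#' Describes the uniform time grid on which an indirect-dimension
#' interferogram is (or would be) sampled: `n_points` complex points spaced
#' `dwell` seconds apart, starting at `t0`. The spectral width is `1/dwell`.
#'
#' @param n_points positive integer number of complex points.
#' @param dwell dwell time in seconds (> 0).
#' @param t0 time of the first point in seconds (default 0).
#' @return an object of class `time_grid`.
#' @examples
#' g <- time_grid(128, dwell = 1 / 2000)
#' spectral_width(g)      # 2000 Hz
#' max(grid_times(g))     # maximum evolution time, (n-1) * dwell
#' @export
time_grid <- function(n_points, dwell, t0 = 0) {
  stopifnot(is_scalar_number(n_points), n_points >= 1, n_points == round(n_points),
            is_scalar_number(dwell), dwell > 0, is_scalar_number(t0))
  structure(list(n_points = as.integer(n_points), dwell = dwell, t0 = t0),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid a `time_grid`.
#' @export
grid_times <- function(grid) {
  grid$t0 + (seq_len(grid$n_points) - 1) * grid$dwell
}

#' @rdname time_grid
#' @export
spectral_width <- function(grid) 1 / grid$dwell

#' @rdname time_grid
#' @export
max_evolution_time <- function(grid) {
  grid$t0 + (grid$n_points - 1) * grid$dwell
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d points, dwell %.6g s (sw %.6g Hz), t0 %.6g s\n",
              x$n_points, x$dwell, 1 / x$dwell, x$t0))
  invisible(x)
}

#' Extend a time grid to more points
#'
#' Same dwell and origin, larger `n_points`; used when model-calculated data
#' are inserted beyond the recorded region.
#' @param grid a `time_grid`.
#' @param n_points new length, at least `grid$n_points`.
#' @keywords internal
extend_grid <- function(grid, n_points) {
  if (n_points < grid$n_points)
    stop("target length ", n_points, " is shorter than the grid (",
         grid$n_points, " points)")
  time_grid(n_points, grid$dwell, grid$t0)
}
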