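#' Complex time-domain interferogram
#'
#' A complex time series on a [time_grid()] together with a logical mask
#' marking which points were experimentally recorded. Truncated uniform
#' sampling is a prefix of `TRUE`s; non-uniform sampling scatters them.
#' Unrecorded positions carry placeholder zeros until a reconstruction
#' method fills them.
#'
#' @param data complex vector.
#' @param grid a [time_grid()] with `n_points == length(data)`.
#' @param sampled logical vector, `TRUE` where experimentally recorded.
#'   Defaults to all recorded.
#' @return an object of class `interferogram`.
#' @export
interferogram <- function(data, grid, sampled = rep(TRUE, length(data))) {
  stopifnot(inherits(grid, "time_grid"))
  data <- as.complex(data)
  sampled <- as.logical(sampled)
  if (length(data) != grid$n_points)
    stop("data length ", length(data), " != grid n_points ", grid$n_points)
  if (length(sampled) != length(data))
    stop("sampled mask length must equal data length")
  structure(list(data = data, grid = grid, sampled = sampled),
            class = "interferogram")
}

#' @rdname interferogram
#' @param fid an `interferogram`.
#' @export
coverage <- function(fid) mean(fid$sampled)

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d points (%d recorded, coverage %.1f%%), sw %.6g Hz\n",
              x$grid$n_points, sum(x$sampled), 100 * coverage(x),
              spectral_width(x$grid)))
  invisible(x)
}

#' Truncate an interferogram to a sampling coverage
#'
#' Marks all points beyond `round(coverage * n)` as unsampled (prefix
#' truncation); the data values at unsampled positions are zeroed
#' placeholders, and reconstruction methods never read them.
#'
#' @param fid an `interferogram`.
#' @param coverage sampling coverage in (0, 1].
#' @export
truncate_fid <- function(fid, coverage) {
  stopifnot(coverage > 0, coverage <= 1)
  n <- fid$grid$n_points
  keep <- round(coverage * n)
  if (keep < 2) stop("coverage ", coverage, " leaves fewer than 2 points")
  mask <- seq_len(n) <= keep
  data <- fid$data
  data[!mask] <- 0 + 0i
  interferogram(data, fid$grid, mask)
}
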