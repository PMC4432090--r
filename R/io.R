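# Plain-text interchange formats. Numbers are serialized with 17 significant
# digits so every IEEE double round-trips bit-exactly.

fmt17 <- function(x) sprintf("%.17g", x)

#' Read and write complex-series tables
#'
#' The native interferogram format: `#`-prefixed `key=value` header lines
#' (`n_points`, `dwell`, optional `t0`, `label`, `bf_mhz`), a column header,
#' then one row per point: 0-based `index`, `real`, `imag`, `sampled` (0/1).
#'
#' @param fid an [interferogram()].
#' @param path file path.
#' @param label axis label stored in the header.
#' @param bf_mhz optional spectrometer base frequency of the axis in MHz
#'   (needed for ppm conversion downstream).
#' @return `read_series()` returns an [interferogram()]; the base frequency,
#'   if present, is attached as attribute `bf_mhz`.
#' @export
write_series <- function(fid, path, label = "indirect", bf_mhz = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# n_points=%d", fid$grid$n_points),
    sprintf("# dwell=%s", fmt17(fid$grid$dwell)),
    sprintf("# t0=%s", fmt17(fid$grid$t0)),
    sprintf("# label=%s", label),
    if (!is.na(bf_mhz)) sprintf("# bf_mhz=%s", fmt17(bf_mhz)),
    "index\treal\timag\tsampled"), con)
  writeLines(sprintf("%d\t%s\t%s\t%d", seq_along(fid$data) - 1L,
                     fmt17(Re(fid$data)), fmt17(Im(fid$data)),
                     as.integer(fid$sampled)), con)
  invisible(path)
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  h <- parse_header(lines)
  for (req in c("n_points", "dwell"))
    if (is.null(h[[req]])) stop("series header missing '", req, "' in ", path)
  body_start <- sum(grepl("^#", lines)) + 1L
  if (lines[body_start] != "index\treal\timag\tsampled")
    stop("line ", body_start, ": expected column header 'index\\treal\\timag\\tsampled'")
  n <- as.integer(h$n_points)
  rows <- lines[(body_start + 1L):length(lines)]
  if (length(rows) != n)
    stop("expected ", n, " data rows, found ", length(rows))
  parts <- strsplit(rows, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 4L)
      stop("line ", body_start + i, ": expected 4 tab-separated fields, got ",
           length(parts[[i]]))
    if (anyNA(suppressWarnings(as.numeric(parts[[i]]))))
      stop("line ", body_start + i, ": non-numeric field")
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 4, byrow = TRUE)
  grid <- time_grid(n, as.numeric(h$dwell), as.numeric(h$t0 %||% 0))
  fid <- interferogram(complex(real = m[, 2], imaginary = m[, 3]), grid,
                       m[, 4] != 0)
  if (!is.null(h$bf_mhz)) attr(fid, "bf_mhz") <- as.numeric(h$bf_mhz)
  fid
}

#' Read and write guide peak lists
#'
#' TSV with header `id  direct_ppm  indirect_hz  linewidth_hz`; `direct_ppm`
#' and `linewidth_hz` may be `NA`.
#'
#' @param peaks a [guide_peak_list()].
#' @param path file path.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "indirect_hz") %in% names(df)))
    stop("peak list ", path, " must have 'id' and 'indirect_hz' columns")
  bad <- which(!is.finite(df$indirect_hz))
  if (length(bad))
    stop("line ", bad[1] + 1L, ": non-numeric indirect_hz")
  guide_peak_list(df$id, df$indirect_hz,
                  df$direct_ppm %||% NA_real_,
                  df$linewidth_hz %||% NA_real_)
}

#' Read and write sampling schedules
#'
#' One 0-based sampled index per line (the hmsIST convention).
#'
#' @param schedule a [sampling_schedule()].
#' @param path file path.
#' @param n_total full grid length (needed on read; not stored in the file).
#' @export
write_schedule <- function(schedule, path) {
  writeLines(as.character(schedule$indices), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, n_total) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- suppressWarnings(as.integer(lines))
  if (anyNA(idx)) stop("line ", which(is.na(idx))[1], ": not an integer index")
  sampling_schedule(idx, n_total)
}

#' Write a spectrum as a two-column table
#'
#' `freq_hz` and the real part, tab separated with a header — convenient for
#' plotting.
#' @param spec an `nmr_spectrum`.
#' @param path file path.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(
    data.frame(freq_hz = spec$freq_hz, intensity = Re(spec$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' Plain `key = value` lines; `#` starts a comment. Values are returned as
#' strings; the caller coerces.
#' @param path file path.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE))
      stop("config line ", i, ": expected 'key = value'")
    key <- trimws(sub("=.*$", "", lines[i]))
    out[[key]] <- trimws(sub("^[^=]*=", "", lines[i]))
  }
  out
}
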