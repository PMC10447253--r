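# Fixed-width window tracks.
#
# A window track is a data.table with columns (chrom, start, end, value,
# n_sites) where windows tile each chromosome in 0-based half-open
# coordinates. The final window of a chromosome may be shorter than `width`
# (its true residual width); `value` is NaN where the statistic is undefined.

#' Build an empty window track
#'
#' Tiles each chromosome with fixed-width, non-overlapping (tumbling) windows
#' in 0-based half-open coordinates. The last window of a chromosome is
#' truncated at the chromosome end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param width window width in bp.
#' @param value initial value for all windows (default `NaN`).
#' @return a `window_track`: a data.table with columns `chrom`, `start`,
#'   `end`, `value`, `n_sites` and attribute `width`.
#' @export
make_window_track <- function(chrom_lengths, width, value = NaN) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) > 0)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive number")
  pieces <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = width)
    data.table(chrom = ch, start = starts, end = pmin(starts + width, L))
  })
  trk <- rbindlist(pieces)
  trk[, `:=`(value = as.numeric(value), n_sites = 0L)]
  as_window_track(trk, width)
}

as_window_track <- function(x, width) {
  setattr(x, "width", width)
  setattr(x, "class", c("window_track", class(x)))
  x
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("window track: %d windows of %s bp on %d chromosome(s)\n",
              nrow(x), format(attr(x, "width"), big.mark = ","),
              length(unique(x$chrom))))
  NextMethod()
}

track_width <- function(trk) {
  w <- attr(trk, "width")
  if (is.null(w)) w <- max(trk$end - trk$start)
  w
}

# windows must be identical (chrom/start/end) across tracks
check_same_windows <- function(...) {
  tracks <- list(...)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref) ||
        !identical(t$chrom, ref$chrom) ||
        !identical(as.numeric(t$start), as.numeric(ref$start)) ||
        !identical(as.numeric(t$end), as.numeric(ref$end)))
      stop("window tracks do not share the same windowing")
  }
  invisible(TRUE)
}

# chromosome lengths implied by a set of positions (1-based), rounded up to
# the window grid, used when the caller does not supply lengths
infer_chrom_lengths <- function(chrom, pos, width) {
  dt <- data.table(chrom = chrom, pos = pos)
  mx <- dt[, .(len = max(pos)), by = chrom]
  setNames(ceiling(mx$len / width) * width, mx$chrom)
}

#' Write a window track as TSV
#'
#' Columns: chrom, start, end, value, n_sites (0-based half-open intervals).
#'
#' @param trk a `window_track`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_track <- function(trk, path) {
  fwrite(as.data.table(trk)[, .(chrom, start, end, value, n_sites)],
         path, sep = "\t")
  invisible(path)
}

#' Read a window track from TSV
#'
#' @param path TSV written by [write_track()].
#' @return a `window_track`.
#' @export
read_track <- function(path) {
  trk <- fread(path, sep = "\t")
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(trk)))
  if (!"n_sites" %in% names(trk)) trk[, n_sites := NA_integer_]
  as_window_track(trk, max(trk$end - trk$start))
}
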