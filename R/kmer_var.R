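# Identity-by-state k-mer variation scores.
#
# A reference genome is compared against a query accession's canonical
# k-mer set (k = 31). Within each 50 kb window the "variation" count is the
# number of maximal runs of consecutive reference k-mer start positions
# whose canonical k-mer is absent from the query set (a single substitution
# creates one absent-run of ~k positions and scores 1). Runs are attributed
# to the window containing the run's start. Windows scoring at or below the
# cut-off (default 30) are identical by state (IBS) with the query.

#' Windowed k-mer variation score against a query k-mer set
#'
#' @param reference genome as `DNAStringSet` or named character vector.
#' @param query_kmers the query accession's `kmer_set`.
#' @param k expected k of the query set (default 31); mismatch is an error.
#' @param width window width in bp (default 50 kb).
#' @return a `window_track` of non-negative integer variation counts; the
#'   track carries attributes `query` and `group` for provenance.
#' @param query,group optional accession id and group label stored on the
#'   track.
#' @export
window_variations <- function(reference, query_kmers, k = 31, width = 5e4,
                              query = query_kmers$label, group = "") {
  if (kmer_k(query_kmers) != k)
    stop("query k-mer set has k = ", kmer_k(query_kmers), ", expected ", k)
  seqs <- as_char_seqs(reference)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  trk <- make_window_track(setNames(nchar(seqs), names(seqs)), width, value = 0)
  for (ch in names(seqs)) {
    v <- cpp_window_variations(seqs[[ch]], query_kmers$ptr, width)
    rows <- which(trk$chrom == ch)
    stopifnot(length(rows) == length(v))
    set(trk, rows, "value", as.numeric(v))
  }
  setattr(trk, "query", query)
  setattr(trk, "group", group)
  trk
}

#' Call identity-by-state segments from a variation track
#'
#' Maximal runs of windows with variation score <= `cutoff`, tolerating up
#' to `merge_gap_windows` consecutive interior windows above the cut-off;
#' runs with fewer than `min_windows` passing windows are dropped. Segments
#' are trimmed to start and end on passing windows.
#'
#' @param track a `window_track` of variation counts.
#' @param cutoff IBS cut-off (default 30; a window scoring exactly 30 is IBS).
#' @param merge_gap_windows interior failures tolerated (default 1; 0
#'   disables gap bridging).
#' @param min_windows minimum passing windows per segment (default 2).
#' @return data.table of segments (chrom, start, end, n_windows, score =
#'   mean variation count over passing windows).
#' @export
ibs_segments <- function(track, cutoff = 30, merge_gap_windows = 1,
                         min_windows = 2) {
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[chrom == ch]
    pass <- !is.na(sub$value) & sub$value <= cutoff
    if (!any(pass)) next
    idx <- which(pass)
    brk <- c(TRUE, diff(idx) > merge_gap_windows + 1)
    seg_id <- cumsum(brk)
    for (s in unique(seg_id)) {
      members <- idx[seg_id == s]
      if (length(members) < min_windows) next
      out[[length(out) + 1]] <- data.table(
        chrom = ch, start = sub$start[min(members)], end = sub$end[max(members)],
        n_windows = length(members), score = mean(sub$value[members]))
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), score = numeric()))
  rbindlist(out)
}

#' Minimum-consensus variation track
#'
#' Per-window minimum across input tracks, with a provenance column naming
#' the accession(s) achieving the minimum (ties comma-joined).
#'
#' @param tracks list of `window_track`s on identical windows; names (or
#'   track `query` attributes) identify the accessions.
#' @return a `window_track` with an extra `argmin` character column.
#' @export
min_consensus <- function(tracks) {
  if (length(tracks) < 1) stop("need at least one track")
  do.call(check_same_windows, unname(tracks))
  ids <- names(tracks)
  if (is.null(ids))
    ids <- vapply(tracks, function(t) {
      q <- attr(t, "query"); if (is.null(q) || !nzchar(q)) NA_character_ else q
    }, character(1))
  ids[is.na(ids)] <- paste0("track", which(is.na(ids)))
  vals <- do.call(cbind, lapply(tracks, function(t) t$value))
  mins <- apply(vals, 1, min)
  argmin <- apply(vals, 1, function(r) paste(ids[r == min(r)], collapse = ","))
  out <- data.table(chrom = tracks[[1]]$chrom, start = tracks[[1]]$start,
                    end = tracks[[1]]$end, value = mins,
                    n_sites = tracks[[1]]$n_sites, argmin = argmin)
  as_window_track(out, track_width(tracks[[1]]))
}

#' Assign a donor group to an introgressed segment
#'
#' For each group, the per-window minimum variation across the group's
#' tracks is computed over the segment's windows; the group's support is the
#' fraction of those windows at or below `cutoff`. The segment is assigned
#' to the group with the highest support if that support is at least
#' `majority` and strictly exceeds every other group's; otherwise
#' `"unassigned"`.
#'
#' @param segment one-row data.frame/list with `chrom`, `start`, `end`.
#' @param tracks_by_group named list; each element is a single
#'   `window_track` (e.g. a group consensus) or a list of tracks.
#' @param cutoff IBS cut-off (default 30).
#' @param majority minimum winning support fraction (default 0.75).
#' @return the winning group label, or `"unassigned"`.
#' @export
assign_donor_group <- function(segment, tracks_by_group, cutoff = 30,
                               majority = 0.75) {
  stopifnot(length(tracks_by_group) >= 1, !is.null(names(tracks_by_group)))
  cons <- lapply(tracks_by_group, function(g) {
    if (inherits(g, "window_track")) g else min_consensus(g)
  })
  do.call(check_same_windows, unname(cons))
  ref <- cons[[1]]
  rows <- which(ref$chrom == segment$chrom &
                  ref$start >= segment$start & ref$end <= segment$end)
  if (!length(rows)) stop("empty segment: no windows inside it")
  support <- vapply(cons, function(t) mean(t$value[rows] <= cutoff), numeric(1))
  best <- which.max(support)
  if (support[best] >= majority && sum(support == support[best]) == 1)
    names(cons)[best]
  else "unassigned"
}
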