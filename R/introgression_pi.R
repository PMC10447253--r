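# Introgression calling from pairwise-diversity tracks.
#
# A candidate introgression in a domesticated accession is a long run of
# 1 Mb windows whose pairwise diversity against a wild donor-race accession
# drops well below the genome-wide level. Three criteria are applied:
# (1) the reduction is continuous over at least `min_span`;
# (2) a control comparison (wild alpha vs domesticated) is NOT reduced over
#     the same run, excluding shared ancestral low-diversity regions;
# (3) the run retains informative data (site or depth coverage), excluding
#     artefacts of unmappable regions.

#' Call introgression segments from a pairwise-diversity track
#'
#' Candidate runs are maximal stretches of windows whose target value is
#' below `reduction_factor` times the genome-wide median of the target
#' track. NaN windows neither qualify nor break a run, and do not count
#' toward the span; runs are trimmed to qualifying windows at both ends. A
#' candidate is retained when (1) the summed width of its qualifying
#' windows is at least `min_span`; (2) the median control value over the
#' run is at least `reduction_factor` times the control's genome-wide
#' median; (3) the median coverage over the run is at least
#' `min_coverage_frac` times the coverage's genome-wide median.
#'
#' @param target_track pairwise diversity, domesticated accession vs donor
#'   candidate (a `window_track`).
#' @param control_track pairwise diversity, same accession vs a control
#'   (alpha-race) accession, on identical windows.
#' @param coverage_track informative-data proxy on identical windows;
#'   default: the `n_sites` channel of the target track.
#' @param reduction_factor theta, the "reduced" multiplier (default 0.25).
#' @param min_span minimum summed qualifying span in bp (default 10 Mb).
#' @param min_coverage_frac criterion-3 multiplier (default 0.5).
#' @return data.table of segments (chrom, start, end, span, score = mean
#'   target/median ratio, crit1-3 logical evidence columns). Only segments
#'   with all three criteria TRUE are returned; attribute `candidates`
#'   holds every criterion-1 candidate with its evidence.
#' @export
call_pi_introgressions <- function(target_track, control_track,
                                   coverage_track = NULL,
                                   reduction_factor = 0.25,
                                   min_span = 1e7,
                                   min_coverage_frac = 0.5) {
  check_same_windows(target_track, control_track)
  if (is.null(coverage_track)) {
    coverage_track <- copy(as.data.table(target_track))
    coverage_track[, value := as.numeric(n_sites)]
    coverage_track <- as_window_track(coverage_track, track_width(target_track))
  } else check_same_windows(target_track, coverage_track)

  med_t <- median(target_track$value[is.finite(target_track$value)])
  med_c <- median(control_track$value[is.finite(control_track$value)])
  med_cov <- median(coverage_track$value[is.finite(coverage_track$value)])
  thr <- reduction_factor * med_t

  cand <- list()
  for (ch in unique(target_track$chrom)) {
    rows <- which(target_track$chrom == ch)
    v <- target_track$value[rows]
    q <- is.finite(v) & v < thr          # qualifying
    neutral <- !is.finite(v)             # NaN: neither qualifies nor breaks
    state <- ifelse(q, 1L, ifelse(neutral, 0L, -1L))
    # runs: maximal stretches without a breaking (-1) window, >= 1 qualifier
    r <- rle(state != -1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      span_idx <- starts[i]:ends[i]
      qi <- span_idx[state[span_idx] == 1L]
      if (!length(qi)) next
      qi_range <- min(qi):max(qi)        # trim edge NaN windows
      w <- rows[qi_range]
      span <- sum(target_track$end[rows[qi]] - target_track$start[rows[qi]])
      run_vals <- target_track$value[w]
      crit1 <- span >= min_span
      crit2 <- median(control_track$value[w], na.rm = TRUE) >=
        reduction_factor * med_c
      crit3 <- median(coverage_track$value[w], na.rm = TRUE) >=
        min_coverage_frac * med_cov
      cand[[length(cand) + 1]] <- data.table(
        chrom = ch,
        start = target_track$start[min(w)], end = target_track$end[max(w)],
        span = span,
        score = mean(run_vals[is.finite(run_vals)]) / med_t,
        crit1 = crit1, crit2 = crit2, crit3 = crit3)
    }
  }
  empty <- data.table(chrom = character(), start = numeric(), end = numeric(),
                      span = numeric(), score = numeric(),
                      crit1 = logical(), crit2 = logical(), crit3 = logical())
  cand <- if (length(cand)) rbindlist(cand) else empty
  out <- cand[crit1 & crit2 & crit3]
  setattr(out, "candidates", cand)
  out[]
}

#' Merge overlapping or adjacent segments
#'
#' @param segments data.table with `chrom`, `start`, `end`.
#' @return merged, non-overlapping segments sorted by position.
#' @export
merge_segments <- function(segments) {
  segments <- as.data.table(segments)
  if (nrow(segments) == 0) return(segments)
  setorder(segments, chrom, start)
  segments[, grp := cumsum(c(TRUE, chrom[-1] != chrom[-.N] |
                               start[-1] > cummax_end(end[-.N], chrom[-.N])))]
  segments[, .(chrom = chrom[1], start = min(start), end = max(end)), by = grp][
    , grp := NULL][]
}

cummax_end <- function(ends, chroms) {
  out <- numeric(length(ends))
  cur <- -Inf; last_ch <- NA_character_
  for (i in seq_along(ends)) {
    if (!identical(chroms[i], last_ch)) { cur <- -Inf; last_ch <- chroms[i] }
    cur <- max(cur, ends[i])
    out[i] <- cur
  }
  out
}

#' Genome fraction covered by segments
#'
#' @param segments merged, non-overlapping segments (`chrom`, `start`, `end`);
#'   overlap is an error.
#' @param genome_length total genome length in bp.
#' @return proportion in `[0, 1]`.
#' @export
genome_fraction <- function(segments, genome_length) {
  segments <- as.data.table(segments)
  if (nrow(segments) == 0) return(0)
  setorder(segments, chrom, start)
  by_ch <- split(segments, segments$chrom)
  for (s in by_ch) {
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("segments overlap; merge them first")
  }
  sum(segments$end - segments$start) / genome_length
}

#' Per-accession introgression summary over a panel
#'
#' @param segment_list named list (accession -> segment data.table).
#' @param genome_length total genome length in bp.
#' @return data.table (accession, n_segments, total_bp, fraction) plus
#'   attributes `mean_fraction` and `range_fraction`.
#' @export
introgression_summary <- function(segment_list, genome_length) {
  out <- rbindlist(lapply(names(segment_list), function(a) {
    s <- segment_list[[a]]
    data.table(accession = a, n_segments = nrow(s),
               total_bp = if (nrow(s)) sum(s$end - s$start) else 0,
               fraction = genome_fraction(merge_segments(s), genome_length))
  }))
  setattr(out, "mean_fraction", mean(out$fraction))
  setattr(out, "range_fraction", range(out$fraction))
  out
}
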