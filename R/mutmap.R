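# Bulked-segregant SNP-index mapping of EMS mutants.
#
# The SNP index of a site is the fraction of reads carrying the alternate
# (mutant) allele in the bulk. Near a recessive causal mutation in a
# phenotype-selected bulk the index approaches 1; unlinked sites sit near
# 0.5. Records with index >= 0.9 are classed homozygous, records with
# index < 0.3 are removed, the rest are heterozygous; window averages over
# 100 kb localize the causal region.

#' Filter raw bulk variants
#'
#' Removal conditions: QUAL < `min_qual`, FS > `max_fs`, MQ < `min_mq`,
#' DP <= `min_dp_gt` (i.e. keep DP > 3), GQ < `min_gq`, SNPs within
#' `indel_bp` of any indel record, and non-biallelic or non-SNP records.
#' Indel records themselves are dropped from the output. Records lacking an
#' annotation column pass that condition (a message notes skipped checks).
#'
#' @param tbl data.table with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `qual`, `fs`, `mq`, `gq`, `depth`, `indel` (logical).
#' @param min_qual,max_fs,min_mq,min_dp_gt,min_gq,indel_bp thresholds
#'   (defaults 30, 40, 40, 3, 20, 10).
#' @return the filtered data.table (SNPs only).
#' @export
filter_bulk_variants <- function(tbl, min_qual = 30, max_fs = 40, min_mq = 40,
                                 min_dp_gt = 3, min_gq = 20, indel_bp = 10) {
  tbl <- as.data.table(tbl)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(tbl)))
  is_indel <- if ("indel" %in% names(tbl)) tbl$indel %in% TRUE
  else nchar(tbl$ref) != 1 | nchar(tbl$alt) != 1
  keep <- !is_indel & nchar(tbl$ref) == 1 & nchar(tbl$alt) == 1 &
    tbl$ref %in% c("A", "C", "G", "T") & tbl$alt %in% c("A", "C", "G", "T")
  skipped <- character(0)
  apply_rule <- function(keep, col, f) {
    if (!col %in% names(tbl)) { skipped <<- c(skipped, col); return(keep) }
    v <- tbl[[col]]
    keep & (is.na(v) | f(v))
  }
  keep <- apply_rule(keep, "qual", function(v) v >= min_qual)
  keep <- apply_rule(keep, "fs", function(v) v <= max_fs)
  keep <- apply_rule(keep, "mq", function(v) v >= min_mq)
  keep <- apply_rule(keep, "depth", function(v) v > min_dp_gt)
  keep <- apply_rule(keep, "gq", function(v) v >= min_gq)
  if (length(skipped))
    message("annotation column(s) absent, treated as passing: ",
            paste(skipped, collapse = ", "))
  if (any(is_indel)) {
    ind <- tbl[is_indel, .(chrom, ipos = pos)]
    snp <- tbl[, .(chrom, low = pos - indel_bp, high = pos + indel_bp, row = .I)]
    hit <- ind[snp, on = .(chrom, ipos >= low, ipos <= high), nomatch = NULL]
    keep[unique(hit$row)] <- FALSE
  }
  tbl[keep]
}

#' Remove varietal SNPs shared with the parent control
#'
#' Drops bulk records whose position carries the same alternate allele in
#' the parent table (background polymorphisms of the parental line, not
#' induced mutations).
#'
#' @param bulk,parent data.tables with `chrom`, `pos`, `alt`.
#' @return the filtered bulk table.
#' @export
remove_varietal <- function(bulk, parent) {
  bulk <- as.data.table(bulk)
  parent <- as.data.table(parent)
  if (nrow(parent) == 0) return(bulk)
  bulk[!parent, on = c("chrom", "pos", "alt")]
}

#' Keep EMS-type transitions
#'
#' Retains G->A and C->T records (the reference-strand signatures of EMS
#' alkylation).
#'
#' @param tbl data.table with `ref`, `alt`.
#' @return the filtered table.
#' @export
ems_filter <- function(tbl) {
  tbl <- as.data.table(tbl)
  tbl[(ref == "G" & alt == "A") | (ref == "C" & alt == "T")]
}

#' SNP-index records and windowed averages
#'
#' Per record, `snp_index = alt_depth / depth`; zero-depth records are
#' rejected with a warning. Records with index < `min_index` (default 0.3)
#' are removed before averaging; the remainder are classed `homozygous`
#' (index >= 0.9) or `heterozygous`. The window value is the mean index of
#' surviving records in the window (NaN where none).
#'
#' @param tbl data.table with `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_depth`.
#' @param width window width in bp (default 100 kb).
#' @param chrom_lengths named lengths; inferred from max positions if NULL.
#' @param min_index removal threshold (default 0.3; an index of exactly 0.3
#'   is kept).
#' @param hom_index homozygous-class threshold (default 0.9).
#' @return `list(records, track)`: records with `snp_index`, `ems_type`,
#'   `class` columns (removed records retained with class "removed");
#'   `track` a `window_track` of mean indices.
#' @export
snp_index_scan <- function(tbl, width = 1e5, chrom_lengths = NULL,
                           min_index = 0.3, hom_index = 0.9) {
  tbl <- as.data.table(tbl)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "depth", "alt_depth") %in%
                  names(tbl)))
  if (any(tbl$depth <= 0)) {
    warning(sum(tbl$depth <= 0), " zero-depth record(s) rejected")
    tbl <- tbl[depth > 0]
  }
  rec <- copy(tbl)
  rec[, snp_index := alt_depth / depth]
  if (any(rec$snp_index < 0 | rec$snp_index > 1))
    stop("alt_depth outside [0, depth]")
  rec[, ems_type := (ref == "G" & alt == "A") | (ref == "C" & alt == "T")]
  rec[, class := fifelse(snp_index < min_index, "removed",
                         fifelse(snp_index >= hom_index, "homozygous",
                                 "heterozygous"))]
  keep <- rec[class != "removed"]
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(rec$chrom, rec$pos, width)
  trk <- make_window_track(chrom_lengths, width, value = NaN)
  if (nrow(keep)) {
    wid <- site_window_id(trk, keep$chrom, keep$pos)
    if (anyNA(wid)) stop("SNP positions outside chrom_lengths")
    agg <- data.table(wid = wid, idx = keep$snp_index)[, .(
      v = mean(idx), n = .N), by = wid]
    trk[agg$wid, `:=`(value = agg$v, n_sites = agg$n)]
  }
  list(records = rec[], track = trk)
}

#' Candidate interval and candidate SNPs
#'
#' The candidate interval is the maximal run of contiguous windows with
#' mean SNP index >= `index_threshold`, tolerating NaN (no-data) windows in
#' the interior; among chromosomes the longest such run (ties: highest mean
#' index) is reported, trimmed to qualifying windows at both ends. The
#' candidate SNPs are the homozygous-class EMS-type records inside it.
#'
#' @param track the window track from [snp_index_scan()].
#' @param records the records table from [snp_index_scan()].
#' @param index_threshold window mean threshold (default 0.9).
#' @return `list(interval, candidates)`; `interval` is NULL (with a message)
#'   when no window qualifies.
#' @export
candidate_interval <- function(track, records, index_threshold = 0.9) {
  best <- NULL
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch)
    v <- track$value[rows]
    q <- is.finite(v) & v >= index_threshold
    neutral <- !is.finite(v)
    state <- ifelse(q, 1L, ifelse(neutral, 0L, -1L))
    r <- rle(state != -1L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      span_idx <- starts[i]:ends[i]
      qi <- span_idx[state[span_idx] == 1L]
      if (!length(qi)) next
      w <- rows[min(qi):max(qi)]
      span <- track$end[max(w)] - track$start[min(w)]
      mean_idx <- mean(track$value[w][is.finite(track$value[w])])
      cand <- list(chrom = ch, start = track$start[min(w)],
                   end = track$end[max(w)], span = span, mean_index = mean_idx)
      if (is.null(best) || span > best$span ||
          (span == best$span && mean_idx > best$mean_index))
        best <- cand
    }
  }
  if (is.null(best)) {
    message("no window reaches the SNP-index threshold")
    return(list(interval = NULL, candidates = NULL))
  }
  records <- as.data.table(records)
  cands <- records[chrom == best$chrom & pos - 1 >= best$start &
                     pos - 1 < best$end & ems_type & class == "homozygous"]
  list(interval = as.data.table(best), candidates = cands)
}
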