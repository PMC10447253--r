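# Centromere boundaries from enrichment-peak density, and LTR
# retrotransposon insertion-age dating.
#
# The functional centromere of each chromosome appears as the densest
# block of CENH3 enrichment peaks; boundaries are resolved at 100 kb from
# the fraction of each bin covered by the peak union. Insertion ages of
# full-length LTR retrotransposons follow from the divergence of the two
# LTRs, identical at insertion: age = K / (2 * rate) with K the
# Jukes-Cantor-corrected distance.

#' Peak coverage density in fixed bins
#'
#' Per bin, the fraction of the bin covered by the union of (possibly
#' overlapping) peak intervals, clipped to the bin.
#'
#' @param peaks data.table/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), or a `GRanges`.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bin bin width in bp (default 100 kb).
#' @return a `window_track` with values in `[0, 1]`.
#' @export
peak_density <- function(peaks, chrom_lengths, bin = 1e5) {
  if (inherits(peaks, "GRanges")) {
    peaks <- data.table(chrom = as.character(GenomicRanges::seqnames(peaks)),
                        start = GenomicRanges::start(peaks) - 1,
                        end = GenomicRanges::end(peaks))
  } else peaks <- as.data.table(peaks)
  trk <- make_window_track(chrom_lengths, bin, value = 0)
  if (nrow(peaks) == 0) return(trk)
  stopifnot(all(peaks$end > peaks$start), all(peaks$start >= 0))
  if (any(!peaks$chrom %in% names(chrom_lengths)) ||
      any(peaks$end > chrom_lengths[peaks$chrom]))
    stop("peaks outside chromosome bounds")
  for (ch in unique(peaks$chrom)) {
    p <- peaks[chrom == ch]
    un <- IRanges::reduce(IRanges::IRanges(start = p$start + 1, end = p$end))
    rows <- which(trk$chrom == ch)
    bins <- IRanges::IRanges(start = trk$start[rows] + 1, end = trk$end[rows])
    ov <- IRanges::findOverlaps(bins, un)
    if (length(ov)) {
      inter <- IRanges::pintersect(bins[S4Vectors::queryHits(ov)],
                                   un[S4Vectors::subjectHits(ov)])
      cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      ri <- rows[as.integer(names(cov))]
      set(trk, ri, "value", as.numeric(cov) / (trk$end[ri] - trk$start[ri]))
    }
  }
  trk
}

#' Call one centromere per chromosome from peak density
#'
#' Bins with density >= `threshold` are grouped, tolerating up to
#' `merge_gap_bins` consecutive sub-threshold bins inside a group; the
#' longest resulting run per chromosome (ties: higher mean density) is the
#' centromere. Chromosomes with no passing bin get an explicit
#' `called = FALSE` row.
#'
#' @param density a `window_track` from [peak_density()].
#' @param threshold minimum bin density (default 0.1).
#' @param merge_gap_bins interior gap tolerance in bins (default 5).
#' @return data.table (chrom, start, end, n_bins, mean_density, called).
#' @export
call_centromere <- function(density, threshold = 0.1, merge_gap_bins = 5) {
  out <- list()
  for (ch in unique(density$chrom)) {
    rows <- which(density$chrom == ch)
    v <- density$value[rows]
    idx <- which(!is.na(v) & v >= threshold)
    if (!length(idx)) {
      out[[length(out) + 1]] <- data.table(chrom = ch, start = NA_real_,
                                           end = NA_real_, n_bins = 0L,
                                           mean_density = NA_real_,
                                           called = FALSE)
      next
    }
    grp <- cumsum(c(TRUE, diff(idx) > merge_gap_bins + 1))
    best <- NULL
    for (g in unique(grp)) {
      members <- idx[grp == g]
      span <- min(members):max(members)
      cand <- list(start = density$start[rows[min(members)]],
                   end = density$end[rows[max(members)]],
                   n_bins = length(span),
                   mean_density = mean(v[span], na.rm = TRUE))
      if (is.null(best) || cand$n_bins > best$n_bins ||
          (cand$n_bins == best$n_bins && cand$mean_density > best$mean_density))
        best <- cand
    }
    out[[length(out) + 1]] <- data.table(chrom = ch, start = best$start,
                                         end = best$end, n_bins = best$n_bins,
                                         mean_density = best$mean_density,
                                         called = TRUE)
  }
  rbindlist(out)
}

#' LTR-LTR divergence with Jukes-Cantor correction
#'
#' For equal-length LTRs, columns are compared directly; unequal lengths
#' are first globally aligned with unit mismatch/gap costs
#' (`Biostrings::pairwiseAlignment`). Gap columns and columns containing N
#' are excluded. `p` is the mismatch proportion over included columns and
#' `K = -(3/4) ln(1 - 4p/3)`; at `p >= 0.75` the correction is saturated
#' and K is NA with `saturated = TRUE`.
#'
#' @param ltr5,ltr3 the two LTR sequences (character or `DNAString`).
#' @return `list(p, K, n_sites, n_mismatch, saturated)`.
#' @export
ltr_divergence <- function(ltr5, ltr3) {
  s5 <- toupper(as.character(ltr5))
  s3 <- toupper(as.character(ltr3))
  if (nchar(s5) == 0 || nchar(s3) == 0) stop("empty LTR sequence")
  if (nchar(s5) != nchar(s3)) {
    aln <- Biostrings::pairwiseAlignment(
      s5, s3, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 0, mismatch = -1, baseOnly = FALSE),
      gapOpening = 0, gapExtension = 1)
    s5 <- as.character(Biostrings::alignedPattern(aln))
    s3 <- as.character(Biostrings::alignedSubject(aln))
  }
  a <- strsplit(s5, "")[[1]]
  b <- strsplit(s3, "")[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(use)) stop("empty alignment: no comparable columns")
  n <- sum(use)
  mm <- sum(a[use] != b[use])
  p <- mm / n
  saturated <- p >= 0.75
  K <- if (saturated) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(p = p, K = K, n_sites = n, n_mismatch = mm, saturated = saturated)
}

#' Insertion age from corrected divergence
#'
#' The two LTRs are identical at insertion and diverge along two branches,
#' so `age = K / (2 * rate)`.
#'
#' @param K Jukes-Cantor distance(s); NA propagates.
#' @param rate substitution rate per site per year (> 0, user-supplied; the
#'   literature value for the host clade must be chosen explicitly).
#' @return age(s) in years.
#' @export
insertion_age <- function(K, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive number (substitutions/site/year)")
  K / (2 * rate)
}

#' Age a table of LTR pairs
#'
#' @param pairs named list of `list(ltr5, ltr3)` elements, or a
#'   `DNAStringSet` whose names end in `_5LTR` / `_3LTR`.
#' @param rate substitution rate per site per year.
#' @return data.table (id, p, K, age, saturated).
#' @export
ltr_age_table <- function(pairs, rate) {
  if (inherits(pairs, "DNAStringSet")) {
    nm <- names(pairs)
    ids <- unique(sub("_(5|3)LTR$", "", nm))
    pairs <- setNames(lapply(ids, function(id) {
      list(ltr5 = as.character(pairs[[paste0(id, "_5LTR")]]),
           ltr3 = as.character(pairs[[paste0(id, "_3LTR")]]))
    }), ids)
  }
  rbindlist(lapply(names(pairs), function(id) {
    d <- ltr_divergence(pairs[[id]]$ltr5, pairs[[id]]$ltr3)
    data.table(id = id, p = d$p, K = d$K, age = insertion_age(d$K, rate),
               saturated = d$saturated)
  }))
}
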