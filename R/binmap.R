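# Skim-seq bin genotyping of RILs.
#
# Sparse parental-allele observations are aggregated per 1 Mb bin and coded
# P1/P2 by the 0.7 proportion rule, H otherwise, NA without data. Crossover
# breakpoints are localized between informative bins (and refined to the
# flanking observed markers when the observations are supplied).

#' Discover parental markers
#'
#' Retains sites where both parents are homozygous, non-missing, have total
#' depth within `[min_dp, max_dp]` and carried-allele depth >= `min_ad`, and
#' carry different alleles.
#'
#' @param vt a `variant_table` holding (at least) the two parents, with DP
#'   and AD matrices.
#' @param p1,p2 parental sample ids.
#' @param min_dp,max_dp depth bounds (defaults 6 and 100).
#' @param min_ad minimum depth of the carried allele (default 3).
#' @return data.table (chrom, pos, ref, alt, p1_allele, p2_allele) with
#'   alleles coded 0 (ref) / 1 (alt); empty with a warning when nothing
#'   passes.
#' @export
discover_parent_markers <- function(vt, p1, p2, min_dp = 6, max_dp = 100,
                                    min_ad = 3) {
  i1 <- sample_index(vt, p1); i2 <- sample_index(vt, p2)
  g1 <- vt$gt[, i1]; g2 <- vt$gt[, i2]
  if (is.null(vt$dp) || is.null(vt$ad_ref) || is.null(vt$ad_alt))
    stop("variant table lacks DP/AD matrices")
  ok_geno <- !is.na(g1) & !is.na(g2) & g1 != GT_HET & g2 != GT_HET & g1 != g2
  dp_ok <- function(i) !is.na(vt$dp[, i]) & vt$dp[, i] >= min_dp &
    vt$dp[, i] <= max_dp
  ad_of <- function(g, i) ifelse(g == 1L, vt$ad_alt[, i], vt$ad_ref[, i])
  keep <- ok_geno & dp_ok(i1) & dp_ok(i2) &
    !is.na(ad_of(g1, i1)) & ad_of(g1, i1) >= min_ad &
    !is.na(ad_of(g2, i2)) & ad_of(g2, i2) >= min_ad
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no markers pass the parental filters")
  data.table(chrom = vt$sites$chrom[keep], pos = vt$sites$pos[keep],
             ref = vt$sites$ref[keep], alt = vt$sites$alt[keep],
             p1_allele = g1[keep], p2_allele = g2[keep])
}

#' Genotype RILs in fixed bins
#'
#' Per RIL and bin, with p1/p2 the counts of observations supporting each
#' parent: code P1 when `p1/(p1+p2) >= ratio`, P2 when
#' `p2/(p1+p2) >= ratio`, H otherwise; NA when fewer than `min_obs`
#' observations. The proportion interpretation of the 0.7 rule is used (a
#' literal count ratio would call the minority parent); the threshold is
#' configurable but must exceed 0.5.
#'
#' @param observations data.table (ril, chrom, pos, parent in 1/2), e.g.
#'   from [simulate_ril()].
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param width bin width in bp (default 1 Mb).
#' @param ratio consensus proportion (default 0.7).
#' @param min_obs minimum observations per bin (default 1).
#' @param ril_ids RIL identifiers (default: `1:max(observations$ril)`), so
#'   RILs without any observation still get all-NA rows.
#' @return a `bin_genotype_matrix`: list with `codes` (RIL x bin character
#'   matrix of "P1"/"P2"/"H"/NA), `n_p1`/`n_p2` support-count matrices, and
#'   `bins` (data.table chrom/start/end).
#' @export
genotype_bins <- function(observations, chrom_lengths, width = 1e6,
                          ratio = 0.7, min_obs = 1, ril_ids = NULL) {
  if (ratio <= 0.5) stop("ratio must exceed 0.5 (the rule is ambiguous below)")
  obs <- as.data.table(observations)
  stopifnot(all(c("ril", "chrom", "pos", "parent") %in% names(obs)))
  bins <- as.data.table(make_window_track(chrom_lengths, width))[
    , .(chrom, start, end)]
  bins[, bin := .I]
  if (is.null(ril_ids))
    ril_ids <- if (nrow(obs)) seq_len(max(obs$ril)) else integer(0)
  nb <- nrow(bins); nr <- length(ril_ids)
  bin_names <- bins[, paste0(chrom, ":", start, "-", end)]
  n_p1 <- n_p2 <- matrix(0L, nr, nb, dimnames = list(ril_ids, bin_names))
  if (nrow(obs)) {
    obs[, start := floor((pos - 1) / width) * width]
    obs <- bins[obs, on = c("chrom", "start")]
    if (anyNA(obs$bin)) stop("observation positions outside chrom_lengths")
    counts <- obs[, .(p1 = sum(parent == 1L), p2 = sum(parent == 2L)),
                  by = .(ril, bin)]
    ri <- match(counts$ril, ril_ids)
    if (anyNA(ri)) stop("observation ril id absent from ril_ids")
    n_p1[cbind(ri, counts$bin)] <- counts$p1
    n_p2[cbind(ri, counts$bin)] <- counts$p2
  }
  tot <- n_p1 + n_p2
  codes <- matrix(NA_character_, nr, nb, dimnames = dimnames(n_p1))
  with_data <- tot >= max(min_obs, 1L)
  prop1 <- ifelse(tot > 0, n_p1 / tot, NA_real_)
  codes[with_data & prop1 >= ratio] <- "P1"
  codes[with_data & (1 - prop1) >= ratio] <- "P2"
  codes[with_data & prop1 < ratio & (1 - prop1) < ratio] <- "H"
  structure(list(codes = codes, n_p1 = n_p1, n_p2 = n_p2, bins = bins[
    , .(chrom, start, end)], width = width),
    class = "bin_genotype_matrix")
}

#' @export
print.bin_genotype_matrix <- function(x, ...) {
  cat(sprintf("bin genotype matrix: %d RILs x %d bins (%s bp)\n",
              nrow(x$codes), ncol(x$codes), format(x$width, big.mark = ",")))
  tab <- table(factor(x$codes, levels = c("P1", "P2", "H")), useNA = "always")
  print(tab)
  invisible(x)
}

#' Find crossover breakpoint intervals
#'
#' For each RIL and chromosome, a breakpoint interval is emitted between
#' every consecutive pair of informative bins with different codes,
#' spanning from the end of the left informative bin to the start of the
#' right one; NA bins in between widen the interval. With the default
#' `het_as_missing = TRUE`, H bins are treated as uninformative for
#' delineation (they widen the interval like NA — an H bin flanked by
#' opposite parental codes is the crossover-bearing bin itself); with
#' `FALSE`, H is a code of its own and transitions into/out of H are
#' breakpoints.
#'
#' When `observations` are supplied, each P1/P2 interval is refined to
#' `[last left-parent observation, first right-parent observation]` within
#' the transition region, which contains the true crossover when the
#' observation error rate is zero.
#'
#' @param mat a `bin_genotype_matrix`.
#' @param observations optional data.table (ril, chrom, pos, parent).
#' @param het_as_missing treat H bins as uninformative (default TRUE).
#' @return data.table (ril, chrom, start, end, left_code, right_code).
#' @export
find_breakpoints <- function(mat, observations = NULL, het_as_missing = TRUE) {
  bins <- mat$bins
  obs <- if (!is.null(observations)) as.data.table(observations)
  out <- list()
  ril_ids <- rownames(mat$codes)
  for (r in seq_len(nrow(mat$codes))) {
    for (ch in unique(bins$chrom)) {
      bi <- which(bins$chrom == ch)
      codes <- mat$codes[r, bi]
      inf <- which(!is.na(codes) & (!het_as_missing | codes != "H"))
      if (length(inf) < 2) next
      chg <- which(codes[inf][-1] != codes[inf][-length(inf)])
      for (j in chg) {
        li <- bi[inf[j]]; ri <- bi[inf[j + 1]]
        start <- bins$end[li]; end <- bins$start[ri]
        lcode <- codes[inf[j]]; rcode <- codes[inf[j + 1]]
        if (!is.null(obs) && lcode %in% c("P1", "P2") &&
            rcode %in% c("P1", "P2")) {
          # refine to flanking observed markers inside the transition region
          reg <- obs[ril == as.integer(ril_ids[r]) & chrom == ch &
                       pos > bins$start[li] & pos <= bins$end[ri]]
          lp <- if (lcode == "P1") 1L else 2L
          lpos <- reg[parent == lp, suppressWarnings(max(pos))]
          rpos <- reg[parent == 3L - lp, suppressWarnings(min(pos))]
          if (is.finite(lpos) && is.finite(rpos) && lpos < rpos) {
            start <- lpos; end <- rpos
          }
        }
        out[[length(out) + 1]] <- data.table(
          ril = as.integer(ril_ids[r]), chrom = ch, start = start, end = end,
          left_code = lcode, right_code = rcode)
      }
    }
  }
  if (!length(out))
    return(data.table(ril = integer(), chrom = character(), start = numeric(),
                      end = numeric(), left_code = character(),
                      right_code = character()))
  rbindlist(out)
}

#' Filter the bin-marker matrix for linkage mapping
#'
#' Drops bins with more than `max_missing` NA fraction across RILs, then
#' collapses groups of bins with identical code vectors (keeping the first
#' of each group; the grouping is recorded in attribute `collapsed`).
#'
#' @param mat a `bin_genotype_matrix`.
#' @param max_missing maximum NA fraction (default 0.30; a bin missing in
#'   exactly 30% of RILs is kept).
#' @return the filtered `bin_genotype_matrix` with attribute `collapsed`
#'   (data.table kept -> members).
#' @export
filter_marker_matrix <- function(mat, max_missing = 0.30) {
  na_frac <- colMeans(is.na(mat$codes))
  keep <- na_frac <= max_missing
  codes <- mat$codes[, keep, drop = FALSE]
  vecs <- apply(codes, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                              collapse = ""))
  first <- !duplicated(vecs)
  groups <- split(colnames(codes), vecs)
  collapsed <- rbindlist(lapply(groups, function(g)
    data.table(kept = g[1], members = paste(g, collapse = ","))))
  sel <- which(keep)[first]
  out <- structure(list(codes = mat$codes[, sel, drop = FALSE],
                        n_p1 = mat$n_p1[, sel, drop = FALSE],
                        n_p2 = mat$n_p2[, sel, drop = FALSE],
                        bins = mat$bins[sel], width = mat$width),
                   class = "bin_genotype_matrix")
  setattr(out, "collapsed", collapsed)
  out
}

#' Export bin genotypes as one-letter codes
#'
#' Writes a TSV of A (P1), B (P2), H, and `-` (missing), one row per RIL,
#' suitable for linkage-mapping software import.
#'
#' @param mat a `bin_genotype_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_linkage_codes <- function(mat, path) {
  m <- mat$codes
  m[is.na(m)] <- "-"
  m[m == "P1"] <- "A"
  m[m == "P2"] <- "B"
  dt <- data.table(ril = rownames(mat$codes))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
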