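# Windowed population statistics on biallelic SNP tables.

#' Hard-filter a variant table
#'
#' Removes (i) SNP clusters: any SNP that belongs to a group of
#' `cluster_n` or more SNPs spanning at most `cluster_bp` bases; (ii) SNPs
#' whose across-sample mean depth falls outside `[min_mean_dp, max_mean_dp]`;
#' (iii) non-biallelic / non-SNP records. Record order is preserved.
#'
#' @param vt a `variant_table`.
#' @param cluster_n,cluster_bp cluster rule: `cluster_n` SNPs within a span of
#'   `cluster_bp` bases (defaults 3 within 10 bp).
#' @param min_mean_dp,max_mean_dp bounds on the across-sample mean DP
#'   (defaults 4 and 15); ignored when the table has no depth matrix.
#' @return the filtered `variant_table`.
#' @export
hard_filter <- function(vt, cluster_n = 3, cluster_bp = 10,
                        min_mean_dp = 4, max_mean_dp = 15) {
  if (n_variants(vt) == 0) return(vt)
  s <- vt$sites
  keep <- nchar(s$ref) == 1 & nchar(s$alt) == 1 &
    s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T")
  # cluster rule: any window of cluster_n consecutive SNPs fitting inside
  # cluster_bp bases flags all its members
  in_cluster <- logical(nrow(s))
  idx_by_chrom <- split(seq_len(nrow(s)), s$chrom)
  for (idx in idx_by_chrom) {
    pos <- s$pos[idx]
    n <- length(pos)
    if (n >= cluster_n) {
      for (i in seq_len(n - cluster_n + 1)) {
        j <- i + cluster_n - 1
        if (pos[j] - pos[i] + 1 <= cluster_bp)
          in_cluster[idx[i:j]] <- TRUE
      }
    }
  }
  keep <- keep & !in_cluster
  if (!is.null(vt$dp)) {
    mdp <- rowMeans(vt$dp, na.rm = TRUE)
    keep <- keep & !is.na(mdp) & mdp >= min_mean_dp & mdp <= max_mean_dp
  }
  subset_variants(vt, keep)
}

# per-site ref/alt allele counts among non-missing haploid-coded calls
site_allele_counts <- function(gt) {
  gt[gt == GT_HET] <- NA_integer_
  alt <- rowSums(gt == 1L, na.rm = TRUE)
  n <- rowSums(!is.na(gt))
  list(ref = n - alt, alt = alt, n = n)
}

# shared windowing helper: aggregate per-site contributions into windows
site_window_id <- function(trk, chrom, pos) {
  width <- track_width(trk)
  tk <- data.table(chrom = trk$chrom, start = as.numeric(trk$start),
                   id = seq_len(nrow(trk)))
  dt <- data.table(chrom = chrom, start = floor((pos - 1) / width) * width)
  tk[dt, on = c("chrom", "start"), id]
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window, pi = sum over SNPs of `a*b / (n*(n-1)/2)` divided by the window
#' width, where `a` and `b` are the ref/alt allele counts among non-missing
#' haploid-coded calls and `n = a + b`. The denominator is the true window
#' width (full `width`, or the residual width for a trailing partial window),
#' i.e. invariant sites count. Sites with fewer than two non-missing calls are
#' skipped. Heterozygous calls are treated as missing (inbred assumption).
#'
#' @param vt a `variant_table`.
#' @param samples sample ids to use (default: all).
#' @param width window width in bp (default 10 kb).
#' @param chrom_lengths named vector of chromosome lengths; inferred from the
#'   largest SNP position per chromosome (rounded up to the grid) when absent.
#' @return a `window_track` with attribute `mean_value`, the genome-wide mean
#'   (total pairwise differences per genome base).
#' @export
window_pi <- function(vt, samples = NULL, width = 1e4, chrom_lengths = NULL) {
  if (width <= 0) stop("width must be positive")
  idx <- if (is.null(samples)) seq_along(vt$samples) else sample_index(vt, samples)
  if (length(idx) < 2) stop("window_pi needs at least two samples")
  cnt <- site_allele_counts(vt$gt[, idx, drop = FALSE])
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(vt$sites$chrom, vt$sites$pos, width)
  trk <- make_window_track(chrom_lengths, width, value = 0)
  ok <- cnt$n >= 2
  contrib <- ifelse(ok, cnt$ref * cnt$alt / (cnt$n * (cnt$n - 1) / 2), 0)
  wid <- site_window_id(trk, vt$sites$chrom, vt$sites$pos)
  if (anyNA(wid[ok])) stop("SNP positions outside chrom_lengths")
  agg <- data.table(wid = wid[ok], contrib = contrib[ok])[, .(
    s = sum(contrib), n = .N), by = wid]
  trk[agg$wid, `:=`(value = agg$s, n_sites = agg$n)]
  trk[, value := value / (end - start)]
  setattr(trk, "mean_value", sum(agg$s) / sum(trk$end - trk$start))
  trk
}

#' Pairwise diversity between two accessions in windows
#'
#' Per window: count of sites where the two samples carry different
#' non-missing (non-heterozygous) alleles, divided by the window width.
#' Windows with no informative site get value `NaN` and `n_sites = 0`.
#'
#' @param vt a `variant_table`.
#' @param sample_x,sample_y sample ids.
#' @param width window width in bp (default 1 Mb).
#' @param chrom_lengths as in [window_pi()].
#' @return a `window_track`; `n_sites` holds the informative-site count.
#' @export
pairwise_diversity <- function(vt, sample_x, sample_y, width = 1e6,
                               chrom_lengths = NULL) {
  if (width <= 0) stop("width must be positive")
  ix <- sample_index(vt, sample_x)
  iy <- sample_index(vt, sample_y)
  x <- haploid_calls(vt$gt[, ix])
  y <- haploid_calls(vt$gt[, iy])
  inf <- !is.na(x) & !is.na(y)
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(vt$sites$chrom, vt$sites$pos, width)
  trk <- make_window_track(chrom_lengths, width, value = NaN)
  wid <- site_window_id(trk, vt$sites$chrom, vt$sites$pos)
  if (anyNA(wid[inf])) stop("SNP positions outside chrom_lengths")
  agg <- data.table(wid = wid[inf], diff = (x != y)[inf])[, .(
    d = sum(diff), n = .N), by = wid]
  trk[agg$wid, `:=`(value = agg$d, n_sites = agg$n)]
  trk[, value := value / (end - start)]
  trk
}

# haploid Weir-Cockerham theta per site for two groups; NA where undefined
wc_theta_sites <- function(n1, p1, n2, p2) {
  nt <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2        # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt
  denom <- msp + (nc - 1) * msg
  theta <- (msp - msg) / denom
  theta[nt - 2 <= 0 | denom == 0] <- NA_real_
  theta
}

#' Windowed Weir-Cockerham F_ST between two groups
#'
#' Per-site Weir-Cockerham estimator on haploid-coded allele counts; the
#' window value is the mean of per-site estimates over SNPs in the window
#' (negative per-site values retained). Sites fixed for the same allele in
#' both groups, and sites where the estimator is undefined, are skipped.
#' `method = "ratio"` gives the ratio-of-sums (variance-component) window
#' estimate instead of the mean of per-site values.
#'
#' @param vt a `variant_table`.
#' @param group1,group2 disjoint character vectors of sample ids (>= 2 each).
#' @param width window width in bp (default 1 Mb).
#' @param chrom_lengths as in [window_pi()].
#' @param method `"mean"` (default) or `"ratio"`.
#' @return a `window_track`; value `NaN` where no usable site exists.
#' @export
window_fst <- function(vt, group1, group2, width = 1e6, chrom_lengths = NULL,
                       method = c("mean", "ratio")) {
  method <- match.arg(method)
  if (width <= 0) stop("width must be positive")
  if (length(intersect(group1, group2)) > 0) stop("groups overlap")
  if (length(group1) < 2 || length(group2) < 2)
    stop("both groups need at least two samples")
  c1 <- site_allele_counts(vt$gt[, sample_index(vt, group1), drop = FALSE])
  c2 <- site_allele_counts(vt$gt[, sample_index(vt, group2), drop = FALSE])
  p1 <- ifelse(c1$n > 0, c1$alt / c1$n, NA_real_)
  p2 <- ifelse(c2$n > 0, c2$alt / c2$n, NA_real_)
  fixed_same <- !is.na(p1) & !is.na(p2) & p1 == p2 & (p1 == 0 | p1 == 1)
  usable <- !is.na(p1) & !is.na(p2) & c1$n >= 1 & c2$n >= 1 & !fixed_same
  theta <- rep(NA_real_, n_variants(vt))
  theta[usable] <- wc_theta_sites(c1$n[usable], p1[usable],
                                  c2$n[usable], p2[usable])
  use <- usable & !is.na(theta)
  if (is.null(chrom_lengths))
    chrom_lengths <- infer_chrom_lengths(vt$sites$chrom, vt$sites$pos, width)
  trk <- make_window_track(chrom_lengths, width, value = NaN)
  wid <- site_window_id(trk, vt$sites$chrom, vt$sites$pos)
  if (method == "mean") {
    agg <- data.table(wid = wid[use], theta = theta[use])[, .(
      v = mean(theta), n = .N), by = wid]
  } else {
    nt <- c1$n + c2$n
    pbar <- (c1$n * p1 + c2$n * p2) / nt
    msp <- c1$n * (p1 - pbar)^2 + c2$n * (p2 - pbar)^2
    msg <- (c1$n * p1 * (1 - p1) + c2$n * p2 * (1 - p2)) / (nt - 2)
    nc <- nt - (c1$n^2 + c2$n^2) / nt
    agg <- data.table(wid = wid[use], a = (msp - msg)[use],
                      b = (msp + (nc - 1) * msg)[use])[, .(
      v = sum(a) / sum(b), n = .N), by = wid]
  }
  trk[agg$wid, `:=`(value = agg$v, n_sites = agg$n)]
  setattr(trk, "mean_value", mean(theta[use]))
  trk
}

#' SNP density per window
#'
#' @param vt a `variant_table`.
#' @param width window width in bp (default 1 Mb).
#' @param chrom_lengths as in [window_pi()].
#' @return a `window_track` whose value is the SNP count per window.
#' @export
snp_density <- function(vt, width = 1e6, chrom_lengths = NULL) {
  if (width <= 0) stop("width must be positive")
  if (is.null(chrom_lengths)) {
    if (n_variants(vt) == 0) stop("empty table needs explicit chrom_lengths")
    chrom_lengths <- infer_chrom_lengths(vt$sites$chrom, vt$sites$pos, width)
  }
  trk <- make_window_track(chrom_lengths, width, value = 0)
  if (n_variants(vt) > 0) {
    wid <- site_window_id(trk, vt$sites$chrom, vt$sites$pos)
    agg <- data.table(wid = wid)[, .N, by = wid]
    trk[agg$wid, `:=`(value = as.numeric(agg$N), n_sites = agg$N)]
  }
  trk
}

#' Generic per-record numeric threshold filters
#'
#' Applies keep-rules of the form `column >= min` / `column <= max` on
#' optional per-record annotation columns of the site table (e.g. GATK-style
#' QD/FS/MQ annotations carried in a VCF). Records lacking the annotation
#' column pass.
#'
#' @param vt a `variant_table` whose `sites` carry annotation columns.
#' @param rules named list, e.g. `list(qd = c(min = 2), fs = c(max = 60))`.
#' @return the filtered `variant_table`.
#' @export
annotation_filter <- function(vt, rules) {
  keep <- rep(TRUE, n_variants(vt))
  for (col in names(rules)) {
    if (!col %in% names(vt$sites)) next
    v <- vt$sites[[col]]
    r <- rules[[col]]
    if (!is.na(r["min"])) keep <- keep & (is.na(v) | v >= r["min"])
    if (!is.na(r["max"])) keep <- keep & (is.na(v) | v <= r["max"])
  }
  subset_variants(vt, keep)
}
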