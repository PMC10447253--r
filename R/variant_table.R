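# Biallelic SNP tables.
#
# Inbred accessions are haploid-coded: genotype 0 = reference allele,
# 1 = alternate allele, 2 = heterozygous (tolerated but treated as missing
# by default in the diversity statistics, matching the selfing biology),
# NA = missing. Depth (DP) and allele depths (AD) are optional per-sample
# matrices aligned with the genotype matrix.

GT_HET <- 2L

#' Construct a variant table
#'
#' @param sites data.table/data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`; additional columns (e.g. `qual`, `fs`, `mq`, `gq`) are kept.
#' @param gt integer matrix, sites x samples, values 0 (ref), 1 (alt),
#'   2 (heterozygous) or NA (missing).
#' @param samples character vector of sample ids (defaults to gt colnames).
#' @param dp,ad_ref,ad_alt optional numeric matrices of total depth and
#'   ref/alt allele depths, same shape as `gt`.
#' @return a `variant_table` object.
#' @export
variant_table <- function(sites, gt, samples = colnames(gt),
                          dp = NULL, ad_ref = NULL, ad_alt = NULL) {
  sites <- as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (nrow(gt) != nrow(sites)) stop("gt and sites have different row counts")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  if (length(samples) != ncol(gt)) stop("samples length must match ncol(gt)")
  colnames(gt) <- samples
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_along(ord))) {
    sites <- sites[ord]
    gt <- gt[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
    if (!is.null(ad_ref)) ad_ref <- ad_ref[ord, , drop = FALSE]
    if (!is.null(ad_alt)) ad_alt <- ad_alt[ord, , drop = FALSE]
  }
  if (anyDuplicated(sites[, .(chrom, pos)]))
    stop("duplicate variant positions within a chromosome")
  vt <- structure(list(sites = sites, gt = gt, samples = samples,
                       dp = dp, ad_ref = ad_ref, ad_alt = ad_alt),
                  class = "variant_table")
  vt
}

#' Number of variant records
#' @param vt a `variant_table`.
#' @export
n_variants <- function(vt) nrow(vt$sites)

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant table: %d biallelic SNPs x %d samples on %d chromosome(s)\n",
              n_variants(x), length(x$samples), length(unique(x$sites$chrom))))
  cat("samples:", paste(head(x$samples, 8), collapse = ", "),
      if (length(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' Subset variant records by row index
#' @param vt a `variant_table`.
#' @param i integer or logical row index.
#' @export
subset_variants <- function(vt, i) {
  variant_table(vt$sites[i], vt$gt[i, , drop = FALSE], vt$samples,
                dp = if (!is.null(vt$dp)) vt$dp[i, , drop = FALSE],
                ad_ref = if (!is.null(vt$ad_ref)) vt$ad_ref[i, , drop = FALSE],
                ad_alt = if (!is.null(vt$ad_alt)) vt$ad_alt[i, , drop = FALSE])
}

sample_index <- function(vt, ids) {
  idx <- match(ids, vt$samples)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# haploid-coded genotype column with heterozygous calls mapped to NA
haploid_calls <- function(gt_col) {
  gt_col[gt_col == GT_HET] <- NA_integer_
  gt_col
}

#' Write a variant table as VCF v4.2
#'
#' Emits GT (diploid-style, homozygous for haploid-coded calls), and DP/AD
#' when depth matrices are present. Positions are written 1-based as stored.
#'
#' @param vt a `variant_table`.
#' @param path output path (plain-text `.vcf`).
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return the path, invisibly.
#' @export
write_vcf <- function(vt, path, contig_lengths = NULL) {
  has_depth <- !is.null(vt$dp) && !is.null(vt$ad_ref) && !is.null(vt$ad_alt)
  fmt <- if (has_depth) "GT:DP:AD" else "GT"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wheatscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_depth)
    hdr <- c(hdr,
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
             '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", vt$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "1/1", "0/1")[vt$gt + 1L],
                   nrow = nrow(vt$gt), ncol = ncol(vt$gt))
  gt_str[is.na(vt$gt)] <- "./."
  if (has_depth) {
    cell <- matrix(paste0(gt_str, ":", as.integer(vt$dp), ":",
                          as.integer(vt$ad_ref), ",", as.integer(vt$ad_alt)),
                   nrow = nrow(gt_str))
    cell[is.na(vt$dp)] <- paste0(gt_str[is.na(vt$dp)], ":.:.,.")
  } else cell <- gt_str
  body <- do.call(paste, c(list(vt$sites$chrom, as.integer(vt$sites$pos), ".",
                                vt$sites$ref, vt$sites$alt, ".", "PASS", ".",
                                fmt),
                           lapply(seq_len(ncol(cell)), function(j) cell[, j]),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses `VariantAnnotation::readVcf()`; retains biallelic SNPs only.
#' Diploid genotypes are haploid-coded (0/0 -> 0, 1/1 -> 1, 0/1 -> 2,
#' ./. -> NA); haploid GT strings ("0", "1") are accepted as well.
#'
#' @param path VCF file.
#' @return a `variant_table` (with DP/AD when the VCF carries them).
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  keep <- S4Vectors::elementNROWS(altl) == 1
  alt <- rep(NA_character_, length(ref))
  alt[keep] <- as.character(unlist(altl[keep]))
  snp <- keep & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  sites <- data.table(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr), ref = ref, alt = alt)
  gt_raw <- VariantAnnotation::geno(vcf)$GT
  code_gt <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0", "0")] <- 0L
    out[g %in% c("1/1", "1|1", "1")] <- 1L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- GT_HET
    out
  }
  gt <- apply(gt_raw, 2, code_gt)
  dim(gt) <- dim(gt_raw)
  dp <- ad_ref <- ad_alt <- NULL
  if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    dp <- VariantAnnotation::geno(vcf)$DP
    storage.mode(dp) <- "numeric"
  }
  if ("AD" %in% names(VariantAnnotation::geno(vcf))) {
    ad <- VariantAnnotation::geno(vcf)$AD
    pick <- function(i) apply(ad, c(1, 2), function(x) {
      x <- x[[1]]
      if (length(x) >= i) as.numeric(x[i]) else NA_real_
    })
    ad_ref <- pick(1); ad_alt <- pick(2)
  }
  vt <- variant_table(sites[snp],
                      gt[snp, , drop = FALSE],
                      samples = colnames(gt_raw),
                      dp = if (!is.null(dp)) dp[snp, , drop = FALSE],
                      ad_ref = if (!is.null(ad_ref)) ad_ref[snp, , drop = FALSE],
                      ad_alt = if (!is.null(ad_alt)) ad_alt[snp, , drop = FALSE])
  vt
}
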