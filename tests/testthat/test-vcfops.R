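# Windowed statistics and hard filters, checked against hand enumeration
# and brute-force pair/ANOVA oracles.

make_vt <- function(pos, gt, dp = NULL, chrom = "c1",
                    ref = "A", alt = "G") {
  n <- length(pos)
  sites <- data.table(chrom = chrom, pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n))
  variant_table(sites, gt, dp = dp)
}

test_that("hard_filter removes SNP clusters (3+ SNPs within 10 bp)", {
  gt <- matrix(c(0L, 1L), 3, 2, byrow = TRUE)
  vt <- make_vt(c(100, 105, 109), gt)
  expect_equal(n_variants(hard_filter(vt)), 0)
  # two SNPs 5 bp apart with mean DP 8 are retained
  gt2 <- matrix(c(0L, 1L), 2, 2, byrow = TRUE)
  vt2 <- make_vt(c(100, 105), gt2, dp = matrix(8, 2, 2))
  expect_equal(n_variants(hard_filter(vt2)), 2)
  # 3 SNPs spanning 11 bp are not a cluster
  vt3 <- make_vt(c(100, 105, 110), gt)
  expect_equal(n_variants(hard_filter(vt3)), 3)
  # empty table passes through
  expect_equal(n_variants(hard_filter(subset_variants(vt, integer(0)))), 0)
})

test_that("hard_filter depth rule on a hand-enumerated 6-record table", {
  gt <- matrix(rep(c(0L, 1L), 6), 6, 2, byrow = TRUE)
  dp <- matrix(c(4, 4, 8, 8, 15, 15, 20, 20, 5, 5, 6, 6), 6, 2, byrow = TRUE)
  vt <- make_vt(c(100, 200, 300, 400, 500, 600), gt, dp = dp)
  out <- hard_filter(vt)
  expect_equal(n_variants(out), 5)                 # the mean-DP 20 record goes
  expect_false(400 %in% out$sites$pos)
  # boundary fidelity: mean DP exactly 4 and exactly 15 are kept
  expect_true(all(c(100, 300) %in% out$sites$pos))
})

test_that("window_pi matches hand-computed examples", {
  # one SNP, two samples differing, width 10 kb -> 1e-4
  vt <- make_vt(5000, matrix(c(0L, 1L), 1, 2))
  trk <- window_pi(vt, width = 1e4, chrom_lengths = c(c1 = 1e4))
  expect_equal(trk$value, 1e-4)
  # monomorphic window -> 0
  vt0 <- make_vt(5000, matrix(c(1L, 1L), 1, 2))
  expect_equal(window_pi(vt0, width = 1e4,
                         chrom_lengths = c(c1 = 1e4))$value, 0)
  # 4 samples split 2/2: (2*2/6)/1e4, checked by explicit pair enumeration
  vt4 <- make_vt(5000, matrix(c(0L, 0L, 1L, 1L), 1, 4))
  got <- window_pi(vt4, width = 1e4, chrom_lengths = c(c1 = 1e4))$value
  oracle <- brute_window_pi(vt4$sites, vt4$gt, 1e4, c(c1 = 1e4))
  expect_equal(got, oracle)
  expect_equal(got, (2 * 2 / 6) / 1e4)
  expect_error(window_pi(vt4, width = 0), "positive")
})

test_that("window_pi equals the pair-enumeration oracle on random tables", {
  for (seed in 1:5) {
    vt <- random_variant_table(20, paste0("S", 1:6), chrom_len = 3e4,
                               seed = seed)
    lens <- c(c1 = 3e4)
    got <- window_pi(vt, width = 1e4, chrom_lengths = lens)
    oracle <- brute_window_pi(vt$sites, vt$gt, 1e4, lens)
    expect_equal(got$value, oracle, tolerance = 1e-12)
  }
})

test_that("pairwise_diversity: identity, symmetry, NaN windows", {
  vt <- random_variant_table(15, paste0("S", 1:4), chrom_len = 4e4, seed = 3)
  lens <- c(c1 = 4e4)
  self <- pairwise_diversity(vt, "S1", "S1", width = 1e4, chrom_lengths = lens)
  expect_true(all(self$value[self$n_sites > 0] == 0))
  xy <- pairwise_diversity(vt, "S1", "S2", width = 1e4, chrom_lengths = lens)
  yx <- pairwise_diversity(vt, "S2", "S1", width = 1e4, chrom_lengths = lens)
  expect_identical(xy$value, yx$value)
  expect_error(pairwise_diversity(vt, "S1", "nope"), "unknown sample")
  # 50 differing sites in one 1 Mb window -> 5e-5
  gt <- cbind(rep(0L, 50), rep(1L, 50))
  vt50 <- make_vt(seq(1000, 50000, by = 1000), gt)
  trk <- pairwise_diversity(vt50, "S1", "S2", width = 1e6,
                            chrom_lengths = c(c1 = 1e6))
  expect_equal(trk$value, 5e-5)
  expect_equal(trk$n_sites, 50L)
  # a window with no informative overlap is NaN with n_sites 0
  gtm <- matrix(c(NA_integer_, 0L), 1, 2)
  vtm <- make_vt(5000, gtm)
  trkm <- pairwise_diversity(vtm, "S1", "S2", width = 1e4,
                             chrom_lengths = c(c1 = 1e4))
  expect_true(is.nan(trkm$value))
  expect_equal(trkm$n_sites, 0L)
})

test_that("window_fst matches the ANOVA oracle and boundary cases", {
  # groups fixed for alternative alleles -> F_ST = 1 per window
  gt <- cbind(matrix(0L, 10, 3), matrix(1L, 10, 3))
  vt <- make_vt(seq(1000, 10000, by = 1000), gt)
  trk <- window_fst(vt, paste0("S", 1:3), paste0("S", 4:6), width = 1e4,
                    chrom_lengths = c(c1 = 1e4))
  expect_equal(trk$value, 1)
  # single site, counts (10 ref, 0 alt) vs (5 ref, 5 alt): matches the
  # independently coded ANOVA estimator
  x1 <- rep(0L, 10); x2 <- c(rep(0L, 5), rep(1L, 5))
  vt1 <- make_vt(5000, matrix(c(x1, x2), 1, 20))
  got <- window_fst(vt1, paste0("S", 1:10), paste0("S", 11:20), width = 1e4,
                    chrom_lengths = c(c1 = 1e4))$value
  expect_equal(got, brute_wc_theta(x1, x2), tolerance = 1e-12)
  expect_error(window_fst(vt1, c("S1", "S2"), c("S2", "S3")), "overlap")
  expect_error(window_fst(vt1, "S1", c("S2", "S3")), "two samples")
})

test_that("window_fst equals the oracle on random tables", {
  for (seed in 1:5) {
    vt <- random_variant_table(20, paste0("S", 1:8), chrom_len = 2e4,
                               seed = seed + 10)
    lens <- c(c1 = 2e4)
    g1 <- paste0("S", 1:4); g2 <- paste0("S", 5:8)
    got <- window_fst(vt, g1, g2, width = 1e4, chrom_lengths = lens)
    # oracle: mean per-site ANOVA theta over usable sites per window
    for (w in seq_len(nrow(got))) {
      rows <- which(vt$sites$pos > got$start[w] & vt$sites$pos <= got$end[w])
      th <- vapply(rows, function(r)
        brute_wc_theta(vt$gt[r, 1:4], vt$gt[r, 5:8]), numeric(1))
      # drop sites fixed for the same allele in both groups
      fixed <- vapply(rows, function(r) {
        a <- vt$gt[r, 1:4]; b <- vt$gt[r, 5:8]
        pa <- mean(a, na.rm = TRUE); pb <- mean(b, na.rm = TRUE)
        !is.nan(pa) && !is.nan(pb) && pa == pb && pa %in% c(0, 1)
      }, logical(1))
      th <- th[!fixed & !is.na(th)]
      if (length(th)) expect_equal(got$value[w], mean(th), tolerance = 1e-12)
      else expect_true(is.nan(got$value[w]))
    }
  }
})

test_that("window_fst is near zero for a panmictic pool", {
  # The per-site Weir-Cockerham estimator carries a small O(1/n) negative
  # finite-sample bias under panmixia (about -0.002 at n = 25 per group),
  # so the null mean is checked against the oracle exactly and against the
  # bias scale, not against a 4-sigma band around literal zero.
  set.seed(99)
  n_sites <- 1e4; n <- 50
  p <- runif(n_sites, 0.1, 0.9)
  gt <- matrix(rbinom(n_sites * n, 1, rep(p, n)), n_sites, n)
  vt <- make_vt(seq_len(n_sites) * 10, gt)
  trk <- window_fst(vt, paste0("S", 1:25), paste0("S", 26:50), width = 1e6,
                    chrom_lengths = c(c1 = 1e6))
  th <- vapply(seq_len(n_sites), function(i)
    brute_wc_theta(gt[i, 1:25], gt[i, 26:50]), numeric(1))
  expect_equal(trk$value[1], mean(th, na.rm = TRUE), tolerance = 1e-12)
  expect_lt(abs(trk$value[1]), 0.01)
})

test_that("snp_density counts and conserves records", {
  gt <- matrix(c(0L, 1L), 7, 2, byrow = TRUE)
  vt <- make_vt(seq(1.1e6, 1.7e6, by = 1e5), gt)
  trk <- snp_density(vt, width = 1e6, chrom_lengths = c(c1 = 3e6))
  expect_equal(trk$value, c(0, 7, 0))
  expect_equal(sum(trk$value), n_variants(vt))
  # empty table -> all-zero track
  empty <- subset_variants(vt, integer(0))
  expect_equal(snp_density(empty, width = 1e6,
                           chrom_lengths = c(c1 = 3e6))$value, c(0, 0, 0))
})

test_that("window boundaries tile chromosomes exactly", {
  trk <- make_window_track(c(a = 2.5e6, b = 1e6), 1e6)
  expect_equal(trk[chrom == "a", end - start], c(1e6, 1e6, 5e5))
  expect_equal(trk[, sum(end - start)], 3.5e6)
  expect_true(all(trk[, start[-1] == end[-.N], by = chrom]$V1))
})

test_that("VCF round-trip preserves sites, genotypes and depths", {
  vt <- random_variant_table(12, paste0("S", 1:3), seed = 7)
  vt$gt[2, 1] <- 2L   # heterozygous survives the round trip
  dp <- matrix(10, 12, 3)
  vt <- variant_table(vt$sites, vt$gt, vt$samples, dp = dp,
                      ad_ref = dp * (vt$gt != 1L), ad_alt = dp * (vt$gt == 1L))
  path <- tempfile(fileext = ".vcf")
  write_vcf(vt, path, contig_lengths = c(c1 = 1e5))
  back <- read_vcf(path)
  expect_equal(back$sites[, .(chrom, pos, ref, alt)],
               vt$sites[, .(chrom, pos, ref, alt)])
  expect_equal(unname(back$gt), unname(vt$gt))
  expect_equal(back$samples, vt$samples)
  expect_equal(unname(back$dp), unname(dp))
})

test_that("annotation_filter applies generic min/max rules", {
  sites <- data.table(chrom = "c1", pos = c(100, 200, 300),
                      ref = "A", alt = "G",
                      qd = c(1.5, 5, NA), fs = c(10, 70, 10))
  vt <- variant_table(sites, matrix(c(0L, 1L), 3, 2, byrow = TRUE))
  out <- annotation_filter(vt, list(qd = c(min = 2), fs = c(max = 60)))
  expect_equal(out$sites$pos, 300)   # NA annotation passes
})
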