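# SNP-index mapping: bulk variant filters, varietal removal, EMS typing,
# index classification and the candidate interval.

test_that("filter_bulk_variants applies removal conditions and indels", {
  tbl <- data.table(
    chrom = "c1",
    pos = c(100, 200, 300, 400, 500, 600, 608, 700, 900, 1000),
    ref = c("G", "G", "G", "G", "G", "GA", "G", "G", "G", "G"),
    alt = c("A", "A", "A", "A", "A", "G", "A", "A", "A", "A"),
    qual = c(50, 20, 50, 50, 50, 50, 50, 50, 50, 50),
    fs = c(10, 10, 50, 10, 10, 10, 10, 10, 10, 10),
    mq = c(60, 60, 60, 30, 60, 60, 60, 60, 60, 60),
    gq = c(99, 99, 99, 99, 10, 99, 99, 99, 99, 99),
    depth = c(30, 30, 30, 30, 30, 30, 30, 3, 30, 30))
  out <- filter_bulk_variants(tbl)
  # removed: 200 (QUAL<30), 300 (FS>40), 400 (MQ<40), 500 (GQ<20),
  # 600 (indel), 608 (within 10 bp of the indel), 700 (DP=3, minDP>3)
  expect_equal(out$pos, c(100, 900, 1000))
  # annotation-absent columns pass, with a message
  expect_message(
    out2 <- filter_bulk_variants(tbl[, .(chrom, pos, ref, alt)]),
    "treated as passing")
  # the indel and its 10 bp neighbourhood are structural, not annotations:
  # both the indel (600) and the nearby SNP (608) still go
  expect_equal(nrow(out2), 8)
})

test_that("snp distance to indel is inclusive at 10 bp", {
  tbl <- data.table(chrom = "c1", pos = c(100, 110, 111),
                    ref = c("GA", "G", "G"), alt = c("G", "A", "A"))
  out <- filter_bulk_variants(tbl)
  expect_equal(out$pos, 111)     # 10 bp away removed, 11 bp away kept
})

test_that("remove_varietal drops shared alternate alleles only", {
  bulk <- data.table(chrom = "c1", pos = c(100, 200, 300),
                     ref = "G", alt = c("A", "A", "A"))
  parent <- data.table(chrom = "c1", pos = c(100, 300), ref = "G",
                       alt = c("A", "T"))
  out <- remove_varietal(bulk, parent)
  expect_equal(out$pos, c(200, 300))   # same-position different allele kept
  expect_equal(remove_varietal(bulk, parent[0]), bulk)
})

test_that("ems_filter keeps only G->A and C->T", {
  tbl <- data.table(chrom = "c1", pos = 1:5 * 100,
                    ref = c("G", "C", "A", "T", "G"),
                    alt = c("A", "T", "G", "A", "C"))
  expect_equal(ems_filter(tbl)$pos, c(100, 200))
})

test_that("snp_index_scan classifies and averages correctly", {
  tbl <- data.table(chrom = "c1", pos = c(1e4, 2e4, 3e4),
                    ref = "G", alt = "A", depth = c(100, 100, 100),
                    alt_depth = c(95, 25, 55))
  scan <- snp_index_scan(tbl, width = 1e5, chrom_lengths = c(c1 = 1e5))
  expect_equal(scan$records$class, c("homozygous", "removed", "heterozygous"))
  # the removed record (0.25) is excluded: mean of (0.95, 0.55) = 0.75
  expect_equal(scan$track$value, 0.75)
  expect_equal(scan$track$n_sites, 2L)
  # boundary fidelity: 0.299 removed, 0.3 kept
  tb <- data.table(chrom = "c1", pos = c(1e4, 2e4), ref = "G", alt = "A",
                   depth = 1000, alt_depth = c(299, 300))
  sc <- snp_index_scan(tb, width = 1e5, chrom_lengths = c(c1 = 1e5))
  expect_equal(sc$records$class, c("removed", "heterozygous"))
  # index bounds and the alt depth = depth case
  tf <- data.table(chrom = "c1", pos = 1e4, ref = "G", alt = "A",
                   depth = 40, alt_depth = 40)
  expect_equal(snp_index_scan(tf, chrom_lengths = c(c1 = 1e5))$records$snp_index, 1)
  expect_warning(
    snp_index_scan(data.table(chrom = "c1", pos = c(1e4, 2e4), ref = "G",
                              alt = "A", depth = c(0, 10),
                              alt_depth = c(0, 9)),
                   chrom_lengths = c(c1 = 1e5)),
    "zero-depth")
})

test_that("window means respect the removal floor", {
  set.seed(71)
  tbl <- data.table(chrom = "c1", pos = sort(sample(1e6, 200)),
                    ref = "G", alt = "A", depth = 30,
                    alt_depth = rbinom(200, 30, runif(200)))
  scan <- snp_index_scan(tbl, width = 1e5, chrom_lengths = c(c1 = 1e6))
  v <- scan$track$value[is.finite(scan$track$value)]
  expect_true(all(v >= 0.3 & v <= 1))
  expect_true(all(scan$records$snp_index >= 0 & scan$records$snp_index <= 1))
})

test_that("candidate_interval finds the run and its homozygous EMS SNPs", {
  # flat unlinked genome at index ~0.5 -> no interval
  flat <- data.table(chrom = "c1", pos = seq(5e4, 9.5e5, by = 5e4),
                     ref = "G", alt = "A", depth = 100, alt_depth = 50)
  sf <- snp_index_scan(flat, width = 1e5, chrom_lengths = c(c1 = 1e6))
  expect_message(res0 <- candidate_interval(sf$track, sf$records),
                 "no window")
  expect_null(res0$interval)
  # single qualifying window -> interval is that window
  one <- data.table(chrom = "c1", pos = c(2.5e5, 6.5e5), ref = "G",
                    alt = "A", depth = 100, alt_depth = c(50, 98))
  s1 <- snp_index_scan(one, width = 1e5, chrom_lengths = c(c1 = 1e6))
  r1 <- candidate_interval(s1$track, s1$records)
  expect_equal(c(r1$interval$start, r1$interval$end), c(6e5, 7e5))
  expect_equal(r1$candidates$pos, 6.5e5)
  # NaN windows inside the run are tolerated; non-EMS records are not
  # listed as candidates
  run <- data.table(chrom = "c1",
                    pos = c(1.5e5, 4.5e5, 5.5e5),
                    ref = c("G", "A", "G"), alt = c("A", "G", "A"),
                    depth = 100, alt_depth = c(95, 96, 97))
  s2 <- snp_index_scan(run, width = 1e5, chrom_lengths = c(c1 = 6e5))
  r2 <- candidate_interval(s2$track, s2$records)
  expect_equal(c(r2$interval$start, r2$interval$end), c(1e5, 6e5))
  expect_equal(r2$candidates$pos, c(1.5e5, 5.5e5))   # the A->G is excluded
})
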