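# Synthetic-data generator: determinism, degenerate inputs, and the
# distributional properties of each sampler.

test_that("make_ancestor is deterministic, validates input, and is uniform", {
  a1 <- make_ancestor(c("1A" = 1000), seed = 7)
  a2 <- make_ancestor(c("1A" = 1000), seed = 7)
  expect_identical(as.character(a1), as.character(a2))
  expect_equal(Biostrings::width(a1), 1000)
  expect_error(make_ancestor(c("1A" = 0)), "positive")
  expect_error(make_ancestor(numeric(0)), "positive")
  # base composition of a 1 Mb sequence: each base within 24-26%
  # (binomial: p = 1/4, sd ~ 0.043%, the band is > 20 sd wide)
  big <- make_ancestor(c("1A" = 1e6), seed = 11)
  comp <- Biostrings::letterFrequency(big, c("A", "C", "G", "T"),
                                      as.prob = TRUE)
  expect_true(all(comp >= 0.24 & comp <= 0.26))
})

test_that("evolve_panel: zero rate, Poisson counts, determinism", {
  lens <- c(c1 = 5e5, c2 = 5e5)
  cfg0 <- sim_config(seed = 5, chrom_lengths = lens,
                     mutation_rate_per_branch = 0,
                     pop_sizes = c(alpha = 2, gamma = 2))
  expect_equal(n_variants(evolve_panel(lens, cfg0)$variants), 0)

  # two single-accession populations -> 4 branches; every mutation is
  # carried by exactly one accession, so all sites segregate and the count
  # is Poisson(4 * mu * L)
  mu <- 2e-5
  cfg <- sim_config(seed = 6, chrom_lengths = lens,
                    mutation_rate_per_branch = mu,
                    pop_sizes = c(alpha = 1, gamma = 1))
  lambda <- 4 * mu * sum(lens)
  n <- n_variants(evolve_panel(lens, cfg)$variants)
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))

  p1 <- evolve_panel(lens, cfg)
  p2 <- evolve_panel(lens, cfg)
  expect_identical(p1$variants$sites, p2$variants$sites)
  expect_identical(p1$variants$gt, p2$variants$gt)
})

test_that("evolve_panel records stay biallelic with distinct positions", {
  lens <- c(c1 = 2e5)
  cfg <- sim_config(seed = 9, chrom_lengths = lens,
                    mutation_rate_per_branch = 5e-4,
                    pop_sizes = c(alpha = 2, beta = 2, gamma = 2, dom = 2))
  vt <- evolve_panel(lens, cfg)$variants
  expect_false(anyDuplicated(vt$sites[, .(chrom, pos)]) > 0)
  expect_true(all(nchar(vt$sites$ref) == 1 & nchar(vt$sites$alt) == 1))
  expect_true(all(vt$sites$ref != vt$sites$alt))
  # segregating: both alleles present
  expect_true(all(rowSums(vt$gt == 1L) > 0 & rowSums(vt$gt == 0L) > 0))
})

test_that("whole-chromosome introgression copies the donor exactly", {
  lens <- c(c1 = 3e5, c2 = 3e5)
  spec <- data.frame(accession = "dom01", chrom = "c1", start = 0,
                     end = 3e5, donor = "gamma")
  cfg <- sim_config(seed = 12, chrom_lengths = lens,
                    mutation_rate_per_branch = 2e-4,
                    pop_sizes = c(alpha = 2, beta = 2, gamma = 2, dom = 2),
                    introgression_spec = spec)
  p <- evolve_panel(lens, cfg)
  donor <- p$truth$introgression_segments$donor_accession[1]
  pd <- pairwise_diversity(p$variants, "dom01", donor, width = 1e5,
                           chrom_lengths = lens)
  expect_true(all(pd[chrom == "c1", value] == 0))
  expect_true(any(pd[chrom == "c2", value] > 0))
})

test_that("overlapping introgression intervals on one accession error", {
  lens <- c(c1 = 3e5)
  spec <- data.frame(accession = "dom01", chrom = "c1",
                     start = c(0, 5e4), end = c(1e5, 1.5e5), donor = "gamma")
  cfg <- sim_config(seed = 1, chrom_lengths = lens,
                    mutation_rate_per_branch = 1e-4,
                    pop_sizes = c(alpha = 2, beta = 2, gamma = 2, dom = 2),
                    introgression_spec = spec)
  expect_error(evolve_panel(lens, cfg), "overlapping")
  expect_error(
    sim_config(chrom_lengths = lens,
               introgression_spec = data.frame(accession = "dom01",
                                               chrom = "c1", start = 0,
                                               end = 4e5, donor = "gamma")),
    "bounds")
})

test_that("simulate_ril: no recombination and full information", {
  lens <- c(c1 = 1e6)
  mk <- data.table(chrom = "c1", pos = seq(1e4, 9.9e5, by = 1e4))
  cfg <- sim_config(seed = 21, chrom_lengths = lens, ril_count = 20,
                    crossovers_per_chrom = 0, obs_rate = 1)
  sim <- simulate_ril(mk, cfg)
  expect_equal(nrow(sim$truth$crossovers), 0)
  per_ril <- sim$observations[, .(n_par = uniqueN(parent)), by = ril]
  expect_true(all(per_ril$n_par == 1))

  # with crossovers, obs_rate 1 and error 0 reconstruct the mosaic exactly
  cfg2 <- sim_config(seed = 22, chrom_lengths = lens, ril_count = 10,
                     crossovers_per_chrom = 2, obs_rate = 1)
  sim2 <- simulate_ril(mk, cfg2, interference_bp = 1e5)
  for (r in 1:10) {
    obs <- sim2$observations[ril == r]
    expect_identical(obs$parent,
                     as.integer(sim2$truth$haplotypes(r, "c1", obs$pos)))
  }
})

test_that("simulate_ril total crossover count is Poisson-consistent", {
  lens <- c(c1 = 5e7)
  mk <- data.table(chrom = "c1", pos = seq(1e5, 4.99e7, by = 1e5))
  cfg <- sim_config(seed = 23, chrom_lengths = lens, ril_count = 200,
                    crossovers_per_chrom = 2, obs_rate = 0.2)
  sim <- simulate_ril(mk, cfg)
  # 200 RILs x Poisson(2): total within 4 sd of 400
  expect_lt(abs(nrow(sim$truth$crossovers) - 400), 4 * sqrt(400))
  # positions strictly increasing per RIL and chromosome
  expect_true(all(sim$truth$crossovers[, .(ok = !is.unsorted(pos, strictly = TRUE)),
                                       by = .(ril, chrom)]$ok))
})

test_that("simulate_bulk: causal fixed, unlinked near 0.5, EMS types", {
  lens <- c(c1 = 1e6, c2 = 1e6)
  b <- simulate_bulk(lens, n_ems = 100, causal = list("c1", 5e5),
                     bulk_size = 30, depth = 1e4, seed = 31)
  tab <- b$table
  causal <- tab[chrom == "c1" & pos == 5e5]
  expect_equal(causal$alt_depth / causal$depth, 1.0)
  # unlinked (other chromosome): c = 0.5; var(p_hat) combines the bulk
  # composition (Bin(60, .5)) and read sampling (Bin(1e4, f))
  unl <- tab[chrom == "c2"]
  sd_u <- sqrt(0.25 / 60 + 0.25 / 1e4)
  expect_true(all(abs(unl$alt_depth / unl$depth - 0.5) < 4 * sd_u))
  expect_true(all((tab$ref == "G" & tab$alt == "A") |
                    (tab$ref == "C" & tab$alt == "T")))
  expect_error(simulate_bulk(lens, 10, list("c1", 10), depth = 0), "depth")
  expect_error(simulate_bulk(lens, 0, list("c1", 10)), "n_ems")
  expect_error(simulate_bulk(lens, 10, list("c1", 2e6)), "outside")
})

test_that("plant_introgressions: identity, whole chromosome, bounds", {
  rec <- make_ancestor(c(a = 5000, b = 5000), seed = 41)
  don <- make_ancestor(c(a = 5000, b = 5000), seed = 42)
  none <- plant_introgressions(rec, don, data.table(chrom = character(),
                                                    start = numeric(),
                                                    end = numeric()))
  expect_identical(as.character(none$genome), as.character(rec))
  whole <- plant_introgressions(rec, don,
                                data.frame(chrom = "a", start = 0, end = 5000))
  expect_identical(as.character(whole$genome[["a"]]),
                   as.character(don[["a"]]))
  expect_identical(as.character(whole$genome[["b"]]),
                   as.character(rec[["b"]]))
  expect_error(plant_introgressions(rec, don,
                                    data.frame(chrom = "a", start = 4000,
                                               end = 6000)),
               "beyond")
})

test_that("planted truth intervals round-trip through BED exactly", {
  segs <- data.table(chrom = c("a", "a", "b"),
                     start = c(0, 2.5e5, 1e4), end = c(1e5, 4e5, 9e4),
                     name = c("s1", "s2", "s3"))
  path <- tempfile(fileext = ".bed")
  write_bed(segs, path)
  back <- read_bed(path)
  expect_equal(back[, .(chrom, start, end, name)], segs)
})

test_that("diverge_ltr_pair: age zero, validation, divergence scales", {
  p0 <- diverge_ltr_pair(2000, 0, 1.3e-8, seed = 51)
  expect_identical(p0$ltr5, p0$ltr3)
  expect_equal(ltr_divergence(p0$ltr5, p0$ltr3)$p, 0)
  expect_error(diverge_ltr_pair(1000, -5, 1.3e-8), "non-negative")
  expect_error(diverge_ltr_pair(1000, 5, 0), "positive")
  young <- diverge_ltr_pair(5000, 1e5, 1.3e-8, seed = 52)
  old <- diverge_ltr_pair(5000, 1e6, 1.3e-8, seed = 53)
  expect_lt(ltr_divergence(young$ltr5, young$ltr3)$p,
            ltr_divergence(old$ltr5, old$ltr3)$p)
})
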