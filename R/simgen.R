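# Synthetic genomes, panels, RIL populations, mutant bulks and LTR pairs
# with planted ground truth.
#
# The generator emulates the data structures of an inbred einkorn-like
# system: a diversity panel of four populations (alpha, beta, gamma,
# domesticated) on the fixed topology ((alpha),(beta,dom),(gamma)) with
# megabase-scale gamma introgression blocks in chosen domesticated
# accessions; a recipient "wheat" genome with planted donor segments; a RIL
# population observed at very low coverage; an EMS mutant bulk; and LTR
# pairs diverged under a Jukes-Cantor clock for a known time. Coordinates
# are 0-based half-open internally; VCF output is 1-based, BED 0-based.

BASES <- c("A", "C", "G", "T")

random_sequence <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Bundles the generator parameters; every field has a default so partial
#' configurations are convenient in tests. `seed` fixes all randomness.
#'
#' @param seed integer seed.
#' @param chrom_lengths named numeric vector, chromosome -> bp.
#' @param mutation_rate_per_branch substitutions/site accumulated on each
#'   branch of the population tree (and on each accession's private branch).
#' @param pop_sizes named integer vector over populations
#'   `alpha`, `beta`, `gamma`, `dom`.
#' @param introgression_spec data.frame with columns `accession`, `chrom`,
#'   `start`, `end` (0-based half-open bp) and `donor` (population id).
#' @param ril_count number of RILs.
#' @param crossovers_per_chrom expected crossovers per chromosome per RIL.
#' @param obs_rate probability that a marker is observed in a given RIL.
#' @param bulk_size plants in the mutant bulk.
#' @param depth sequencing depth (reads/site) for depth-bearing outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 1e6),
                       mutation_rate_per_branch = 1e-5,
                       pop_sizes = c(alpha = 4, beta = 4, gamma = 4, dom = 8),
                       introgression_spec = NULL,
                       ril_count = 100,
                       crossovers_per_chrom = 1.5,
                       obs_rate = 0.5,
                       bulk_size = 30,
                       depth = 10) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (mutation_rate_per_branch < 0 || mutation_rate_per_branch >= 1)
    stop("mutation_rate_per_branch must be in [0, 1)")
  if (!is.null(introgression_spec)) {
    introgression_spec <- as.data.frame(introgression_spec)
    stopifnot(all(c("accession", "chrom", "start", "end", "donor") %in%
                    names(introgression_spec)))
    bad <- !(introgression_spec$chrom %in% names(chrom_lengths)) |
      introgression_spec$start < 0 |
      introgression_spec$end > chrom_lengths[introgression_spec$chrom] |
      introgression_spec$end <= introgression_spec$start
    if (any(bad)) stop("introgression interval outside chromosome bounds")
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 mutation_rate_per_branch = mutation_rate_per_branch,
                 pop_sizes = pop_sizes,
                 introgression_spec = introgression_spec,
                 ril_count = ril_count,
                 crossovers_per_chrom = crossovers_per_chrom,
                 obs_rate = obs_rate, bulk_size = bulk_size, depth = depth),
            class = "sim_config")
}

#' Generate a random ancestral genome
#'
#' Uniform-random sequence over A/C/G/T per chromosome; deterministic for a
#' given seed.
#'
#' @param chrom_lengths named numeric vector of lengths (bp), all > 0.
#' @param seed integer seed.
#' @return a named `Biostrings::DNAStringSet`.
#' @export
make_ancestor <- function(chrom_lengths, seed = 1) {
  if (length(chrom_lengths) == 0 || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  set.seed(seed)
  seqs <- vapply(chrom_lengths, random_sequence, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(chrom_lengths)))
}

# fixed population topology ((alpha),(beta,dom),(gamma)): shared branches
# per population lineage
POP_BRANCHES <- list(alpha = c("b_alpha"),
                     beta = c("b_betadom", "b_beta"),
                     dom = c("b_betadom", "b_dom"),
                     gamma = c("b_gamma"))

#' Evolve a diversity panel from an ancestor
#'
#' Substitutions accumulate on each branch of the fixed population tree
#' ((alpha),(beta,dom),(gamma)) and on one private branch per accession:
#' Poisson(rate x genome length) mutations at uniform positions under an
#' infinite-sites scheme (collisions redrawn), so every record stays
#' biallelic. Accessions are fully inbred (haploid-coded homozygotes).
#' Domesticated accessions listed in `introgression_spec` then receive the
#' donor accession's alleles across the specified intervals; sites
#' monomorphic after this copy are dropped so the table contains exactly the
#' segregating sites.
#'
#' @param ancestor a `DNAStringSet` (ref alleles read from the sequence) or a
#'   named numeric vector of chromosome lengths (sequence-free mode: ref/alt
#'   drawn at random).
#' @param config a [sim_config()]; `introgression_spec$donor` may name a
#'   population (first accession of that population donates) or a specific
#'   accession id.
#' @param with_depth simulate per-sample DP/AD matrices (Poisson depth around
#'   `config$depth`). Default FALSE.
#' @return `list(variants = variant_table, truth = list(...))`; the truth
#'   carries `introgression_segments` (accession, chrom, start, end, donor,
#'   donor_accession) and `donor_of` the donor accession used per segment.
#' @export
evolve_panel <- function(ancestor, config, with_depth = FALSE) {
  set.seed(config$seed)
  chrom_lengths <- if (inherits(ancestor, "DNAStringSet"))
    setNames(Biostrings::width(ancestor), names(ancestor)) else ancestor
  pops <- names(config$pop_sizes)
  stopifnot(all(pops %in% names(POP_BRANCHES)))
  acc <- unlist(lapply(pops, function(p)
    sprintf("%s%02d", p, seq_len(config$pop_sizes[[p]]))))
  acc_pop <- rep(pops, config$pop_sizes)
  branches <- c(unique(unlist(POP_BRANCHES[pops])), paste0("priv_", acc))
  carrier <- lapply(branches, function(b) {
    if (startsWith(b, "priv_")) which(acc == sub("^priv_", "", b))
    else which(vapply(acc_pop, function(p) b %in% POP_BRANCHES[[p]], logical(1)))
  })

  L <- sum(chrom_lengths)
  rate <- config$mutation_rate_per_branch
  n_mut <- rpois(length(branches), rate * L)
  total <- sum(n_mut)
  if (total == 0) {
    sites <- data.table(chrom = character(), pos = numeric(),
                        ref = character(), alt = character())
    gt <- matrix(integer(), 0, length(acc), dimnames = list(NULL, acc))
    return(list(variants = variant_table(sites, gt, acc),
                truth = list(introgression_segments = NULL)))
  }
  # infinite sites: one distinct genomic position per mutation
  gpos <- sample(L, total, replace = FALSE)       # 1-based over concatenated genome
  offs <- cumsum(c(0, as.numeric(chrom_lengths)))
  ci <- findInterval(gpos, offs + 1)
  chrom <- names(chrom_lengths)[ci]
  pos <- gpos - offs[ci]                          # 1-based within chromosome
  if (inherits(ancestor, "DNAStringSet")) {
    ref <- vapply(seq_along(gpos), function(i)
      as.character(Biostrings::subseq(ancestor[[chrom[i]]], pos[i], pos[i])),
      character(1))
  } else {
    ref <- sample(BASES, total, replace = TRUE)
  }
  # alternate allele: uniform among the three non-reference bases
  alt <- BASES[(match(ref, BASES) - 1L + sample(3L, total, replace = TRUE)) %% 4L + 1L]
  branch_of <- rep(seq_along(branches), n_mut)
  gt <- matrix(0L, total, length(acc), dimnames = list(NULL, acc))
  for (bi in seq_along(branches)) {
    rows <- which(branch_of == bi)
    if (length(rows) && length(carrier[[bi]]))
      gt[rows, carrier[[bi]]] <- 1L
  }

  truth_seg <- NULL
  spec <- config$introgression_spec
  if (!is.null(spec) && nrow(spec) > 0) {
    key <- paste(spec$accession)
    for (a in unique(key)) {
      iv <- spec[key == a, , drop = FALSE]
      iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
      for (ch in unique(iv$chrom)) {
        ivc <- iv[iv$chrom == ch, , drop = FALSE]
        if (nrow(ivc) > 1 && any(ivc$start[-1] < ivc$end[-nrow(ivc)]))
          stop("overlapping introgression intervals on accession ", a)
      }
    }
    donor_acc <- vapply(as.character(spec$donor), function(d) {
      if (d %in% acc) d
      else if (d %in% pops) acc[acc_pop == d][1]
      else stop("unknown donor: ", d)
    }, character(1))
    for (i in seq_len(nrow(spec))) {
      tgt <- match(spec$accession[i], acc)
      if (is.na(tgt)) stop("unknown target accession: ", spec$accession[i])
      don <- match(donor_acc[i], acc)
      rows <- which(chrom == spec$chrom[i] &
                      pos - 1 >= spec$start[i] & pos - 1 < spec$end[i])
      gt[rows, tgt] <- gt[rows, don]
    }
    truth_seg <- data.table(accession = spec$accession, chrom = spec$chrom,
                            start = spec$start, end = spec$end,
                            donor = spec$donor, donor_accession = donor_acc)
  }

  seg <- rowSums(gt == 1L) > 0 & rowSums(gt == 0L) > 0
  sites <- data.table(chrom = chrom, pos = as.numeric(pos), ref = ref, alt = alt)
  dp <- ad_ref <- ad_alt <- NULL
  if (with_depth) {
    dp <- matrix(rpois(total * length(acc), config$depth), total, length(acc))
    ad_alt <- dp * (gt == 1L)
    ad_ref <- dp - ad_alt
  }
  vt <- variant_table(sites[seg], gt[seg, , drop = FALSE], acc,
                      dp = if (with_depth) dp[seg, , drop = FALSE],
                      ad_ref = if (with_depth) ad_ref[seg, , drop = FALSE],
                      ad_alt = if (with_depth) ad_alt[seg, , drop = FALSE])
  list(variants = vt,
       truth = list(introgression_segments = truth_seg),
       populations = setNames(acc_pop, acc))
}

# crossover positions with positive interference (hard-core process):
# Poisson count, uniform positions redrawn until all pairwise distances are
# >= min_dist; if the full set cannot be placed, points are added greedily
# one at a time and the achieved count may fall short of the request
# (interference caps crossover numbers, as it does in real chromosomes)
draw_crossovers <- function(n, chrom_len, min_dist, tries = 100) {
  if (n == 0) return(numeric(0))
  if (n == 1) return(runif(1, 0, chrom_len))
  for (i in seq_len(tries)) {
    p <- sort(runif(n, 0, chrom_len))
    if (all(diff(p) >= min_dist)) return(p)
  }
  placed <- runif(1, 0, chrom_len)
  attempts <- 0L
  while (length(placed) < n && attempts < 200L * n) {
    attempts <- attempts + 1L
    cand <- runif(1, 0, chrom_len)
    if (all(abs(cand - placed) >= min_dist)) placed <- c(placed, cand)
  }
  sort(placed)
}

#' Simulate a skim-sequenced RIL population
#'
#' Each RIL is a fully homozygous mosaic of the two parental haplotypes
#' (F-infinity selfing approximation) with Poisson-distributed crossovers at
#' uniform positions, subject to a minimum inter-crossover distance
#' (`interference_bp`) emulating the strong positive crossover interference
#' of Triticeae. Each marker is observed in a given RIL with probability
#' `obs_rate`; an observation reports the true parental allele, flipped with
#' probability `error_rate`.
#'
#' @param markers data.table/data.frame with columns `chrom`, `pos` (1-based)
#'   at which the two parents carry different alleles.
#' @param config a [sim_config()] supplying `chrom_lengths`, `ril_count`,
#'   `crossovers_per_chrom`, `obs_rate` and `seed`.
#' @param error_rate observation error (default 0).
#' @param interference_bp minimum distance between crossovers (default 5 Mb,
#'   truncated to half the chromosome).
#' @return `list(observations, truth)`: `observations` is a data.table
#'   (ril, chrom, pos, parent in 1/2); `truth$crossovers` a data.table
#'   (ril, chrom, pos) with strictly increasing positions per chromosome, and
#'   `truth$haplotypes` a function(ril, chrom, pos) returning the true parent.
#' @export
simulate_ril <- function(markers, config, error_rate = 0,
                         interference_bp = 5e6) {
  set.seed(config$seed + 1L)
  markers <- as.data.table(markers)
  stopifnot(all(c("chrom", "pos") %in% names(markers)))
  setkey(markers, chrom, pos)
  chroms <- names(config$chrom_lengths)
  co_list <- vector("list", config$ril_count * length(chroms))
  obs_list <- vector("list", config$ril_count * length(chroms))
  start_parent <- matrix(sample(1:2, config$ril_count * length(chroms),
                                replace = TRUE),
                         nrow = config$ril_count,
                         dimnames = list(NULL, chroms))
  k <- 0L
  for (r in seq_len(config$ril_count)) {
    for (ch in chroms) {
      k <- k + 1L
      len <- config$chrom_lengths[[ch]]
      n_co <- rpois(1, config$crossovers_per_chrom)
      co <- draw_crossovers(n_co, len, min(interference_bp, len / 2))
      mk <- markers[chrom == ch]
      if (nrow(mk)) {
        seg <- findInterval(mk$pos, co)            # segment index per marker
        par <- ifelse(seg %% 2 == 0, start_parent[r, ch],
                      3L - start_parent[r, ch])
        seen <- runif(nrow(mk)) < config$obs_rate
        if (any(seen)) {
          par_obs <- par[seen]
          if (error_rate > 0) {
            flip <- runif(sum(seen)) < error_rate
            par_obs[flip] <- 3L - par_obs[flip]
          }
          obs_list[[k]] <- data.table(ril = r, chrom = ch,
                                      pos = mk$pos[seen], parent = par_obs)
        }
      }
      if (length(co))
        co_list[[k]] <- data.table(ril = r, chrom = ch, pos = co)
    }
  }
  observations <- rbindlist(obs_list)
  if (nrow(observations) == 0)
    observations <- data.table(ril = integer(), chrom = character(),
                               pos = numeric(), parent = integer())
  crossovers <- rbindlist(co_list)
  if (nrow(crossovers) == 0)
    crossovers <- data.table(ril = integer(), chrom = character(),
                             pos = numeric())
  hap_fun <- function(ril_id, chrom_id, positions) {
    co <- sort(crossovers[ril == ril_id & chrom == chrom_id, pos])
    seg <- findInterval(positions, co)
    ifelse(seg %% 2 == 0, start_parent[ril_id, chrom_id],
           3L - start_parent[ril_id, chrom_id])
  }
  list(observations = observations,
       truth = list(crossovers = crossovers, start_parent = start_parent,
                    haplotypes = hap_fun))
}

# Haldane map function: recombination fraction from genetic distance d (Morgans)
haldane_c <- function(d_morgans) (1 - exp(-2 * d_morgans)) / 2

#' Simulate an EMS mutant-bulk allele-depth table
#'
#' Plants in the bulk are homozygous mutant at the causal position. At any
#' other EMS SNP, each of the `2 * bulk_size` chromosomes carries the mutant
#' allele with probability `1 - c`, where the recombination fraction `c` is
#' the Haldane transform of the bp distance times `morgans_per_bp` (capped at
#' 0.5; SNPs on other chromosomes are unlinked, c = 0.5). The observed
#' alternate depth is Binomial(depth, bulk allele frequency). All planted
#' SNPs are G->A or C->T transitions on the reference strand.
#'
#' @param reference named numeric vector of chromosome lengths, or a
#'   `DNAStringSet` (only lengths are used; ref bases are drawn from G/C as
#'   EMS targets either way).
#' @param n_ems total number of EMS SNPs including the causal one (>= 1).
#' @param causal list/vector `(chrom, pos)` of the causal SNP (1-based).
#' @param bulk_size plants in the bulk.
#' @param depth reads per site (> 0).
#' @param seed integer seed.
#' @param morgans_per_bp genetic map rate used for linkage decay. The default
#'   5e-6 makes EMS mutations effectively unlinked beyond a few hundred kb,
#'   mirroring the sparse-per-map-unit EMS landscape in which a mutant-bulk
#'   scan isolates a single candidate (see the methods vignette).
#' @return `list(table, truth)`: `table` has columns chrom, pos, ref, alt,
#'   depth, alt_depth; `truth$causal_snp` the planted causal site.
#' @export
simulate_bulk <- function(reference, n_ems, causal, bulk_size = 30,
                          depth = 30, seed = 1, morgans_per_bp = 5e-6) {
  if (depth <= 0) stop("depth must be positive")
  if (n_ems < 1) stop("n_ems must be >= 1")
  chrom_lengths <- if (inherits(reference, "DNAStringSet"))
    setNames(Biostrings::width(reference), names(reference)) else reference
  causal_chrom <- as.character(causal[[1]])
  causal_pos <- as.numeric(causal[[2]])
  if (!causal_chrom %in% names(chrom_lengths) ||
      causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]])
    stop("causal position outside the reference")
  set.seed(seed)
  L <- sum(chrom_lengths)
  offs <- cumsum(c(0, as.numeric(chrom_lengths)))
  gpos <- sample(L, n_ems - 1, replace = FALSE)
  ci <- findInterval(gpos, offs + 1)
  chrom <- c(causal_chrom, names(chrom_lengths)[ci])
  pos <- c(causal_pos, gpos - offs[ci])
  ref <- sample(c("G", "C"), n_ems, replace = TRUE)
  alt <- ifelse(ref == "G", "A", "T")
  d_bp <- ifelse(chrom == causal_chrom, abs(pos - causal_pos), Inf)
  cfrac <- pmin(haldane_c(d_bp * morgans_per_bp), 0.5)
  cfrac[1] <- 0
  n_chrom <- 2L * bulk_size
  mutant <- rbinom(n_ems, n_chrom, 1 - cfrac)
  mutant[1] <- n_chrom
  freq <- mutant / n_chrom
  alt_depth <- rbinom(n_ems, depth, freq)
  alt_depth[1] <- depth                      # causal site fixed in the bulk
  tab <- data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    depth = as.numeric(depth), alt_depth = as.numeric(alt_depth))
  setkey(tab, chrom, pos)
  list(table = tab,
       truth = list(causal_snp = list(chrom = causal_chrom, pos = causal_pos)))
}

#' Plant donor segments into a recipient genome
#'
#' Output equals the recipient outside the segments and the donor inside
#' them (0-based half-open coordinates on the shared chromosome ids).
#'
#' @param recipient,donor named `DNAStringSet`s sharing chromosome ids.
#' @param segments data.frame with columns `chrom`, `start`, `end`.
#' @return `list(genome, truth)`: the planted `DNAStringSet` and a truth
#'   data.table of the planted intervals (BED-compatible).
#' @export
plant_introgressions <- function(recipient, donor, segments) {
  segments <- as.data.table(segments)
  out <- as.character(recipient)
  if (nrow(segments)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(segments)))
    for (i in seq_len(nrow(segments))) {
      ch <- segments$chrom[i]
      if (!ch %in% names(out) || !ch %in% names(donor))
        stop("segment chromosome absent from recipient or donor: ", ch)
      s <- segments$start[i]; e <- segments$end[i]
      if (s < 0 || e > nchar(out[[ch]]) || e <= s)
        stop("segment beyond chromosome end: ", ch, ":", s, "-", e)
      substr(out[[ch]], s + 1, e) <-
        substr(as.character(donor[[ch]]), s + 1, e)
    }
  }
  list(genome = Biostrings::DNAStringSet(out),
       truth = segments[, .(chrom, start, end)])
}

#' Mutate a sequence under a Jukes-Cantor clock
#'
#' Each site changes with probability `3/4 * (1 - exp(-4/3 * rate * time))`
#' to a base drawn uniformly from the three alternatives.
#' @noRd
jc_mutate <- function(seq, subs_per_site) {
  p_change <- 3 / 4 * (1 - exp(-4 / 3 * subs_per_site))
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < p_change)
  if (length(hit)) {
    b[hit] <- BASES[(match(b[hit], BASES) - 1L +
                       sample(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  }
  paste(b, collapse = "")
}

#' Simulate a diverged LTR pair
#'
#' The two LTR copies start identical and each accumulates substitutions
#' under a Jukes-Cantor process with `rate * age_years` expected
#' substitutions per site.
#'
#' @param length LTR length in bp.
#' @param age_years insertion age (>= 0).
#' @param rate substitution rate per site per year (> 0).
#' @param seed integer seed.
#' @return `list(ltr5, ltr3, age)` with sequences as character strings.
#' @export
diverge_ltr_pair <- function(length, age_years, rate, seed = 1) {
  if (age_years < 0) stop("age must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  set.seed(seed)
  anc <- random_sequence(length)
  list(ltr5 = jc_mutate(anc, rate * age_years),
       ltr3 = jc_mutate(anc, rate * age_years),
       age = age_years)
}

#' Write segments as BED (0-based half-open)
#'
#' @param segments data.frame with `chrom`, `start`, `end` and optionally
#'   `name` and `score`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed <- function(segments, path) {
  segments <- as.data.table(segments)
  gr <- GenomicRanges::GRanges(segments$chrom,
                               IRanges::IRanges(start = segments$start + 1,
                                                end = segments$end))
  if ("name" %in% names(segments)) names(gr) <- segments$name
  if ("score" %in% names(segments)) gr$score <- segments$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as 0-based half-open segments
#'
#' @param path BED file.
#' @return data.table with `chrom`, `start`, `end` (+ name/score if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) out[, name := gr$name]
  if (!is.null(gr$score)) out[, score := gr$score]
  out
}
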