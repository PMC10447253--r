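# wheatscan

Windowed population-genetic scans and k-mer methods for inbred wheat
genomes: detecting chromosomal introgressions, genotyping skim-sequenced
RIL populations, mapping EMS mutants from bulked segregants, calling
centromere boundaries and dating LTR retrotransposon insertions — with a
synthetic-data generator that plants known ground truth so every stage is
testable without external data.

## Who this is for

Groups working with selfing (inbred) cereal panels — einkorn, other
diploid wheats and their relatives — who need the recurring bespoke steps
of such studies as tested, reusable components rather than one-off
scripts:

- **Introgression detection, two ways.**
  *k-mer mapping*: build canonical k-mer sets (k = 51) per species/panel,
  subtract the shared k-mers, scan a recipient genome for species-specific
  k-mer coverage in windows, and call segments where donor-specific mean
  coverage is >= 5 while the reciprocal set is depleted, merging regions
  no more than 1 Mb apart.
  *k-mer variation (IBS)*: count variations of a reference against a query
  k-mer database (k = 31) in 50 kb windows, call identity-by-state
  segments at the <= 30 cut-off, build minimum-consensus tracks and assign
  donor groups.
- **Windowed statistics from SNP tables**: nucleotide diversity
  (10 kb windows), pairwise diversity between accessions (1 Mb),
  Weir–Cockerham F_ST (1 Mb, per-site estimates averaged per window), SNP
  density, and hard filters (SNP clusters of 3+ in 10 bp; mean depth
  outside [4, 15]; biallelic only).
- **Pairwise-diversity introgression calling** with the three-criteria
  rule: continuous reduction >= 10 Mb, no reduction in the alpha-race
  control comparison, and no loss of informative data.
- **Skim-seq bin genotyping**: parental marker filters (depth 6–100,
  allele depth >= 3, homozygous, opposite alleles), 1 Mb consensus bins by
  the 0.7 proportion rule (P1/P2/H), crossover breakpoint intervals
  refined to flanking markers, and marker-matrix filtering (>30% missing
  dropped; identical markers collapsed).
- **MutMap mapping**: SNP-index per record (index >= 0.9 homozygous,
  < 0.3 removed), EMS-type (G->A, C->T) selection, varietal-SNP removal,
  100 kb window averages and the candidate interval with its candidate
  SNPs.
- **Centromeres and LTR dating**: enrichment-peak density at 100 kb and
  longest-dense-run boundary calling; LTR–LTR divergence with
  Jukes–Cantor correction `K = -(3/4) ln(1 - 4p/3)` and insertion age
  `K / (2 * rate)`.

## Worked example

Simulate a diversity panel (four populations on the fixed topology
((alpha),(beta,dom),(gamma))) with an 18 Mb gamma introgression planted in
a domesticated accession, then recover it with the three-criteria
pairwise-diversity scan:

```r
library(wheatscan)

lens <- c(chr1 = 5e7, chr2 = 5e7)
cfg <- sim_config(
  seed = 1, chrom_lengths = lens, mutation_rate_per_branch = 1e-5,
  pop_sizes = c(alpha = 4, beta = 4, gamma = 4, dom = 8),
  introgression_spec = data.frame(accession = "dom01", chrom = "chr2",
                                  start = 12e6, end = 30e6, donor = "gamma"))
panel <- evolve_panel(lens, cfg)
panel$variants
#> variant table: 24902 biallelic SNPs x 20 samples on 2 chromosome(s)

donor   <- panel$truth$introgression_segments$donor_accession
target  <- pairwise_diversity(panel$variants, "dom01", donor,
                              width = 1e6, chrom_lengths = lens)
control <- pairwise_diversity(panel$variants, "dom01", "alpha01",
                              width = 1e6, chrom_lengths = lens)
call_pi_introgressions(target, control)
#>     chrom   start   end    span score  crit1  crit2  crit3
#> 1:   chr2 1.2e+07 3e+07 1.8e+07     0   TRUE   TRUE   TRUE
```

The planted segment comes back at window resolution with all three
criteria satisfied; its `score` is the mean diversity in the run relative
to the genome-wide median (0: the segment is an exact donor copy), and
`genome_fraction()` turns calls into per-accession percentages (18.0%
here). The LTR clock on a simulated pair:

```r
pair <- diverge_ltr_pair(length = 5000, age_years = 5e5, rate = 1.3e-8,
                         seed = 2)
d <- ltr_divergence(pair$ltr5, pair$ltr3)
insertion_age(d$K, rate = 1.3e-8)
#> p = 0.01220, K = 0.01230, estimated age = 473089 years
```

## Command line

An installed `wheatscan` script (see `inst/exec/`) dispatches the stages
and writes a JSON run manifest (inputs, parameters, seed, output
checksums) next to each output:

```sh
wheatscan simulate --config sim.yaml --outdir out/
wheatscan stats pairdiv --vcf out/panel.vcf --sample-x dom01 --sample-y gamma01 \
          --window 1000000 --out out/target.tsv
wheatscan introgression pi-scan --target out/target.tsv --control out/control.tsv \
          --out out/segments.bed
wheatscan kmer count|diff|scan|call ...
wheatscan ibs scan|consensus|segments ...
wheatscan binmap genotype|breakpoints ...
wheatscan mutmap index|candidates ...
wheatscan centromere density|call ...
wheatscan ltr age --fasta pairs.fa --rate 1.3e-8 --out ages.tsv
```

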