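---
title: "wheatscan: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheatscan: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wheatscan bundles the computational procedures that recur in population
genomics of inbred wheats: detecting chromosomal introgressions (by k-mers
and by windowed diversity), genotyping low-coverage recombinant inbred
lines (RILs) in bins, mapping EMS mutants from bulked segregants, and two
smaller utilities (centromere boundaries from enrichment-peak density, LTR
retrotransposon dating). This vignette explains each model, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the methods are
genuinely underdetermined.

## 1. The data model

All accessions are treated as fully inbred selfers: a genotype is haploid
coded (0 = reference allele, 1 = alternate). Heterozygous calls are
tolerated in the containers but treated as missing by the diversity
statistics, because residual heterozygosity in einkorn-type panels is
noise relative to the inbred signal. Windows are fixed-width, tumbling and
0-based half-open; the final window of a chromosome keeps its true
residual width, which also serves as the denominator of per-bp statistics
there. VCF input/output is 1-based; BED output 0-based half-open.

## 2. Windowed diversity statistics (`window_pi`, `pairwise_diversity`, `window_fst`)

Per-site nucleotide diversity uses the unbiased pair count: with `a`
reference and `b` alternate alleles among `n = a + b` non-missing calls,
the site contributes `a*b / (n(n-1)/2)`; a window's pi is the sum of
contributions divided by the full window width (invariant sites count —
the convention of the common VCF toolchains). Pairwise diversity between
two accessions is simply the count of differing informative sites per
window width; windows without informative overlap are NaN, not zero,
because absence of data is not identity.

F_ST is the Weir–Cockerham estimator on haploid allele counts, computed
per site and averaged per window ("mean fixation index"), with negative
per-site estimates retained; a ratio-of-sums variant is available via
`method = "ratio"`. Two numerical notes: (i) sites fixed for the same
allele in both groups carry no information and are skipped; (ii) the
per-site estimator has a small negative O(1/n) finite-sample bias under
panmixia (about -0.002 at n = 25 per group). The null-panel test therefore
checks agreement with an independent ANOVA implementation exactly and
bounds the magnitude of the null mean, rather than pretending the
estimator is exactly unbiased.

The hard filter mirrors standard resequencing practice: SNP clusters
(three or more SNPs within a 10 bp span — all members removed),
across-sample mean depth outside [4, 15], and non-biallelic records.
"Within 10 bp" is implemented as span `pos_last - pos_first + 1 <= 10`,
so positions 100/105/109 form a cluster and 100/105/110 do not.

## 3. Pairwise-diversity introgression calling (`call_pi_introgressions`)

A donor-race introgression in a domesticated accession appears as a long
run of 1 Mb windows with pairwise diversity against a donor-race accession
far below the genome-wide level. Three criteria are applied:

1. a continuous reduction spanning at least `min_span` (default 10 Mb);
2. no corresponding reduction in a control comparison (accession vs a
   wild alpha-race accession), excluding shared ancestral low-diversity
   regions;
3. retained informative data over the run (default: the informative-site
   channel of the target track; an external depth track can be supplied),
   excluding artefacts of unmappable regions.

The magnitude of "reduction" is not quantified in the source method, so it
is an explicit parameter: a window qualifies when its value is below
`reduction_factor` (theta, default 0.25) times the genome-wide median of
the same track. The default passes near-identical segments (diversity
near 0) and fails background windows (near the median) with a wide margin;
the monotonicity property (candidate runs shrink as theta decreases) is
tested. NaN windows neither qualify nor break a run and do not count
toward the span — a no-data window should not interrupt an otherwise
continuous signal, nor manufacture span. Segment boundaries are reported
at window resolution.

## 4. k-mer mapping (`count_kmers`, `specific_kmers`, `window_specific_coverage`, `call_kmer_segments`)

Canonical k-mers (k = 51 by default) are 2-bit packed into 128-bit
integers; a set is a sorted unique vector with binary-search membership
(src/kmers.cpp). "Mapping full-length k-mers with no mismatches" is
mathematically identical to exact canonical membership of the k-mer
starting at each genome position, so no external aligner is involved.
Coverage is base-level depth — each matching k-mer covers its k bases —
and a window's value is its mean per-base depth; `mode = "starts"` gives
match-start counts instead. Segments are called where donor-specific mean
coverage is at least 5 and the reciprocal ("other"-specific) coverage is
depleted; "depleted" is unquantified in the source, so the default ceiling
is a mean depth of 1. Qualifying regions no more than 1 Mb apart are
merged, and merged segments shorter than `min_len` (50 kb) are dropped.
With donor divergence around 1%, roughly `1 - 0.99^51 ~ 40%` of donor
positions carry a donor-specific k-mer, so donor windows sit near depth
20 — comfortably above the threshold — while chimeric k-mers spanning
segment junctions belong to neither set and keep boundaries sharp to
within k - 1 bp.

## 5. k-mer variation / IBS (`window_variations`, `ibs_segments`, `min_consensus`, `assign_donor_group`)

The reference genome is scored in 50 kb windows against a query
accession's k = 31 set: a "variation" is a maximal run of consecutive
reference positions whose canonical k-mer is absent from the query (one
substitution creates one absent-run of about k positions and scores 1).
The external pipeline this emulates does not publish its internal scoring,
so the maximal-run definition is this package's own, stated prominently;
the IBS cut-off (<= 30 per window) remains configurable to compensate.
Runs are attributed to the window containing their start (deterministic,
order-independent). Segment calling tolerates one interior above-cutoff
window by default (`merge_gap_windows = 1`) so single noisy windows do not
fragment segments; set 0 to disable. Donor-group assignment uses the
per-group minimum-consensus track: a group supports a segment window when
its minimum variation is within the cut-off, and the segment is assigned
to the group with the highest support fraction only if that fraction
reaches `majority` (default 0.75) and strictly exceeds all others —
ties are "unassigned" rather than guessed.

## 6. Bin genotyping of skim-sequenced RILs (`binmap`)

Parental markers require both parents homozygous, non-missing, depth in
[6, 100], carried-allele depth >= 3, and opposite alleles. Sparse RIL
observations are aggregated per 1 Mb bin; with p1/p2 the per-parent
support counts, the bin is coded P1 when `p1/(p1+p2) >= 0.7`, P2
symmetrically, H otherwise, NA below `min_obs` (default 1, exposed — the
source does not state one). The published rule reads "P1/P2 >= 0.7"
literally as a count ratio, which would call P1 exactly when P2
observations dominate; the proportion reading is the only one consistent
with "proportions of P1 and P2 within the window", and the boundary case
(7 of 10) codes P1.

Breakpoints are reported as intervals, not points. At bin resolution the
interval runs from the end of the left informative bin to the start of the
right one, NA bins widening it; the frozen behaviour for codes
(P1, P1, P2, P2) on 1 Mb bins is the zero-width boundary [2 Mb, 2 Mb]. How
H bins were treated is not stated in the source and is genuinely
consequential: an H bin flanked by opposite parental codes is almost
always the crossover-bearing bin itself. The default
(`het_as_missing = TRUE`) therefore treats H as uninformative for
delineation, so it widens the interval like NA; `FALSE` restores the
literal any-code-change rule. When the sparse observations are passed in,
each interval is refined to [last left-parent marker, first right-parent
marker], which provably contains the crossover at observation error 0.

Two detection limits are inherent and documented rather than hidden:
a crossover whose terminal segment contains no informative bin (e.g. in
the last few hundred kb of a chromosome) is invisible to any
bin-genotyping observer, and a bin containing a crossover has no single
true parental code. Accuracy is therefore scored over called P1/P2 bins
against the majority parent of the bin, with H calls on crossover bins
counted as correct statements, and crossover-recovery guarantees are
stated for observable crossovers (informative, disagreeing flanks).

## 7. MutMap SNP-index mapping (`mutmap`)

The SNP index of a bulk record is `alt_depth / depth`. Records are classed
homozygous at index >= 0.9, removed below 0.3 and heterozygous between;
removed records are excluded before 100 kb window averaging, so window
means live in [0.3, 1]. Upstream filters: QUAL >= 30, FS <= 40, MQ >= 40,
DP > 3, GQ >= 20, no SNP within 10 bp of an indel, biallelic SNPs only —
all expressed as removal conditions; records lacking an annotation column
pass that condition with a logged message, because re-deriving aligner
annotations from reads is out of scope. Varietal background SNPs are
removed by alternate-allele identity with the parent control, and only
EMS-type (G->A, C->T) transitions are retained. The candidate interval is
the longest run of contiguous windows with mean index >= 0.9 (NaN windows
tolerated inside, ties broken by higher mean), and the candidate SNPs are
the homozygous EMS records inside it. Heterozygous-class records
contribute to window means but are never candidates.

## 8. Centromeres and the LTR clock

Centromere boundaries come from enrichment-peak density at 100 kb
resolution: each bin's value is the fraction covered by the clipped union
of peak intervals (whether the original rule used covered fraction or
peak counts at 100 kb is not stated; covered fraction is used here, and
the conservation property `sum(value x width) = union length` is tested).
One centromere per chromosome is the longest run of bins at or above
`threshold` (default 0.1), bridging gaps up to 5 bins; both knobs are
artifact decisions and configurable, and chromosomes with no passing bin
get an explicit "none" record.

LTR pairs are identical at insertion; divergence dates the insertion.
Equal-length LTRs are compared column-wise; unequal lengths are first
globally aligned with unit mismatch/gap costs. Gap and N columns are
excluded; `p` is the mismatch fraction, `K = -(3/4) ln(1 - 4p/3)`
(Jukes–Cantor — the minimal standard correction; raw `p` is also reported
so other clocks can be applied), and `age = K / (2 rate)`. The
substitution rate is a required argument with no hidden default: the
appropriate clade rate must be chosen by the user. `p >= 0.75` saturates
the correction and is flagged rather than extrapolated.

## 9. The synthetic-data generator (`simgen`) — what it emulates

The panel generator is the package's testing instrument, not a coalescent
simulator. Populations follow the fixed topology ((alpha),(beta,dom),
(gamma)) — the minimal structure in which the domesticated pool is
closest to beta while carrying detectable gamma introgressions. Each tree
branch and each accession's private branch accumulates
Poisson(rate x genome length) substitutions at uniform distinct positions
(infinite sites, keeping every record biallelic); introgression means
copying the donor accession's alleles across the stated interval. The
generator is sequence-free by default (only the variant table is
materialized), which is what makes 20-seed panels of 40 accessions over
7 x 50 Mb chromosomes affordable; literal ancestor sequences are supported
for the k-mer pipelines. It does not emulate linkage disequilibrium,
recombination within the panel, depth-dependent genotyping error or
reference bias — a green recovery test establishes that the callers invert
the generator's model at realistic signal/noise, not that they are robust
to artefacts the generator never produces.

RIL mosaics use Poisson crossover counts with uniform positions under a
hard-core (minimum separation) constraint, default 5 Mb, reflecting the
strong positive crossover interference of Triticeae; when a drawn count
cannot be placed at that separation the achieved count falls short rather
than violating the constraint. Without interference, double crossovers
inside one 1 Mb bin are invisible to any bin-level observer and no
breakpoint guarantee could hold. Observations are Bernoulli per marker per
RIL (`obs_rate`), reporting the true parental allele with an optional
error rate (default 0).

The mutant bulk fixes the causal site in all plants and gives every other
EMS site a bulk frequency of `1 - c`, with `c` the Haldane transform of
physical distance times `morgans_per_bp`, capped at 0.5; read support is
Binomial(depth, frequency). The default map rate (5e-6 Morgans/bp over a
3 x 30 Mb genome with 200 EMS SNPs) is chosen once so that the EMS density
per map unit is below one mutation per 0.1 Morgan — the regime the source
study was in, where the candidate interval contained a single EMS
mutation. A physically scaled map with 200 SNPs would put tens of EMS SNPs
within the linked neighbourhood of the causal site and no method could
report a unique candidate; the distance-decay of the SNP index remains
visible over the first few hundred kb. This is a deliberate property of
the stated test world, fixed before the recovery tests were run.

LTR pairs evolve from a common random sequence under the Jukes–Cantor
process with `rate x age` expected substitutions per site per copy, so the
clock estimator is exercised against its own generative model.

## 10. Reproducibility and limits

Every generator takes an explicit seed and is byte-deterministic given
it. The acceptance suite (tests/testthat/test-acceptance.R) encodes the
recovery and threshold-fidelity properties at fixed scales; it runs in
about 5–6 minutes on one CPU. Known limitations: no mismatch-tolerant
k-mer matching, no imputation or genotype-likelihood handling, no
read-level simulation, breakpoint refinement assumes error-free
observations, and the Fst machinery is limited to two groups per call.
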