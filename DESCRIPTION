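Package: wheatscan
Title: Introgression Detection, Skim-Seq Bin Genotyping and Mutant Mapping
    for Inbred Wheat Panels
Version: 0.1.0
Authors@R:
    person("wheatscan", "developers", email = "wheatscan@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic scans and k-mer methods for detecting
    chromosomal introgressions in inbred wheat genomes, together with the
    companion genotyping and mapping procedures used around them. Provides
    canonical k-mer set construction and species-specific k-mer coverage scans,
    identity-by-state variation scores in fixed windows, windowed nucleotide
    diversity, pairwise diversity and Weir-Cockerham Fst from biallelic SNP
    tables, hard filters for SNP clusters and depth, a pairwise-diversity
    introgression caller, 1 Mb bin genotyping of low-coverage recombinant
    inbred lines with crossover breakpoint localization, bulked-segregant
    SNP-index mapping of EMS mutants, centromere boundary calling from
    enrichment-peak density, LTR retrotransposon insertion-age dating, and a
    synthetic-data generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
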