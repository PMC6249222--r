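Package: tnseqr
Title: Transposon-Insertion Sequencing Essentiality Analysis for Archaeal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide inference of essential genes from transposon-insertion
    sequencing (Tn-seq) libraries, modelled on saturating Tn5 mutagenesis of a
    circular archaeal chromosome. Provides read filtering and insertion-site
    extraction from alignments, per-gene essentiality scoring by a dual-score
    consensus (an expected-reads log2 fold change and an insertion-count
    essentiality index over trimmed gene bodies), automatic bimodal cutoff
    detection by kernel density valley finding, repeat masking, library
    saturation planning, insertion-site nucleotide-bias profiling, and a
    downstream phyletic toolkit (presence/absence category assignment,
    permutation nulls, cross-organism essential-gene crosstabs, and exact
    small-scale Fitch parsimony with bootstrap support). A synthetic-data
    generator emulates the statistical structure of real libraries with ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
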