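Package: chromSurvey
Title: Chromosome Survey Sequencing Analysis with Planted-Truth Simulation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for low-coverage survey sequencing of
    flow-sorted chromosome arms, modelled on the workflows used for large
    repeat-rich cereal chromosomes. Classifies unassembled reads into a
    repeat/gene ledger through a staged similarity cascade, estimates
    sequence coverage, coding fraction and gene counts, maps coding reads
    onto related reference gene orders to build a "genome zipper" virtual
    gene order with reciprocal-best-hit reliability codes and deletion-bin
    collinearity checks, discovers conserved miRNA precursors by
    homology search plus hairpin folding and the minimal folding free
    energy index (MFEI), and scaffolds assembly contigs along unigenes.
    A synthetic-data module generates chromosome arms, reads,
    pseudo-assemblies, reference trios, unigenes and bin-mapped markers
    with full planted truth, so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'chromSurvey-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'similarity.R'
    'classify.R'
    'genecontent.R'
    'io.R'
    'mirna.R'
    'scaffold.R'
    'simulate.R'
    'zipper.R'
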