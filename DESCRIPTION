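Package: crisprseq
Title: Amplicon Sequencing Analysis of Cell-Specific CRISPR/Cas9 Genome Edits
Version: 1.0.0
Authors@R: person("CRISPR-seq", "Maintainers", email = "crisprseq@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting rare, cell-specific CRISPR/Cas9 genome edits in
    mosaic animals by deep amplicon sequencing. Models the two-step PCR library
    construction (gene-specific tailed primers, then indexed Illumina adapter
    primers) with in-silico PCR against a reference; simulates truth-labelled
    FASTQ read sets from mosaic populations in which only a fraction of cells
    carry PAM-proximal deletions, including amplification dropout of alleles
    whose deletions remove a primer site; aligns reads with a semi-global
    affine-gap aligner emitting SAM with left-normalized indels; profiles
    per-position coverage and base absence rates; and calls whether editing
    occurred against a matched unedited control. Also implements Q-neuroblast
    migration genetics statistics: five-position neuron tallies, a two-sided
    Fisher exact test, and additive-expectation synergy tests for double
    mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
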