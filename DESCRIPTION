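Package: haploscan
Title: Haplotype-Based Detection of Subtle Allelic Imbalance from Sequencing Data
Version: 0.1.0
Authors@R:
    person("Alex", "Renard", email = "alex.renard@example.org",
           role = c("aut", "cre"))
Description: Detects chromosomal allelic imbalance (amplification, deletion,
    copy-neutral loss of heterozygosity) present in small fractions of a
    heterogeneous DNA sample, using allele-specific read depths at
    heterozygous sites from exome or whole-genome sequencing. Reference
    allele frequencies are compared against statistically estimated germline
    haplotypes by frequency-based phasing; a three-state hidden Markov model
    aggregates the per-marker concordance evidence into posterior
    probabilities of imbalance and segmented event calls, tolerating switch
    errors in the haplotype estimates. Includes a synthetic-data simulator
    for exome-like and genome-like designs so that detection sensitivity can
    be measured across aberrant-cell fractions without external data, and a
    command-line interface for the detect/simulate/power workflow. No paired
    normal sample is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
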