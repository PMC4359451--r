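Package: capturecall
Title: Individual-, Population- and LD-Aware Genotype Calling for
    Targeted Sequencing with Heterogeneous Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Likelihood-based single-nucleotide variant calling for
    targeted (capture) sequencing experiments with heterogeneous
    per-site, per-sample coverage. Implements an individual-based
    Bayesian single-marker caller with a reference-mismatch prior and
    multi-allelic support, a population-based caller with a neutral-model
    polymorphism prior and Hardy-Weinberg allele-frequency estimation by
    EM, and an LD-aware genotype refiner built on a Li-Stephens
    haplotype-copying hidden Markov model that can exploit flanking chip
    genotypes. Ships the accompanying quality-control ladder (genotype
    filters, feature-based site ranking, fixed-size call-set selection,
    imputation R-squared filter), call-set evaluation statistics
    (transition/transversion ratio, heterozygote mismatch rates,
    missingness, singleton and down-sampling analyses, exact tests), and
    a fully seeded synthetic cohort generator with truth tracking for
    method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    e1071,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
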