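Package: cohortsig
Title: Cohort-Level Somatic Mutational Signature Analysis by Bootstrapped NMF
Version: 0.1.0
Authors@R:
    person("Cohortsig", "Developers", email = "cohortsig@example.org",
           role = c("aut", "cre"))
Description: Builds pyrimidine-collapsed 96-trinucleotide mutation catalogs
    from somatic single-nucleotide variants, decomposes them into mutational
    signatures by bootstrapped non-negative matrix factorization under the
    generalized Kullback-Leibler divergence, selects the factorization rank
    by cophenetic correlation and Hoyer sparseness, annotates recovered
    signatures against named archetypes (smoking, UVA/UVB, APOBEC/kataegis,
    MSI-low/high, non-CpG-island), and relates per-sample signature loads to
    clinical covariates. Ships a synthetic-data generator with planted ground
    truth (signatures, exposures, genomes, CpG-island tracks, covariates) so
    the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
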