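Package: hybridscape
Title: Demographic Inference and Hybridization Analysis for Hybrid
    Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hybrid speciation and contact-zone
    hybridization from reduced-representation SNP data, built around an
    alpine butterfly complex of two parental and two hybrid-origin taxa.
    Reads and filters diploid SNP genotype matrices (VCF and two-row
    STRUCTURE text), builds joint allele-frequency spectra with
    hypergeometric projection and folding, computes expected spectra for
    a library of two- and three-population divergence scenarios (strict
    isolation, isolation with migration, ancient migration, secondary
    contact, hybrid speciation, and secondary gene flow, with optional
    growth and two-class heterogeneous migration) by structured-coalescent
    Monte Carlo, fits them by Poisson composite likelihood with AIC-based
    model selection, estimates per-individual maximum-likelihood hybrid
    indices and interspecific heterozygosity in contact zones, and
    provides Nei Fst, Schoener's D climatic-niche overlap, and a
    synthetic-data generator with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
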