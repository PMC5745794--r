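Package: coalsweep
Title: Coalescent Simulation, Demographic Inference, Sweep Scans and QTL
    Mapping for Two-Population Plant Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying local adaptation in selfing plants with
    two-population resequencing panels and experimental crosses. Provides a
    structured-coalescent simulator for two-deme demographic histories with
    size changes, divergence and timed migration windows (with or without
    recombination via a Hudson-style ancestral recombination graph);
    GATK-style hard filtering of variant records; sliding-window nucleotide
    diversity, Watterson's theta and Hudson's FST; folded joint site
    frequency spectra; composite-likelihood demographic fitting with AIC
    model choice and parametric bootstrap; selective-sweep scans by an
    SFS-based composite likelihood ratio and by the LD-based omega
    statistic with simulation-calibrated cutoffs; and F2 interval mapping
    of quantitative traits with permutation thresholds. All analyses can be
    exercised end to end on synthetic data generated by the package itself.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
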