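Package: quantvar
Title: Partitioning Genotypic Values and Genetic Variance at One and Two Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fisher's partition of genotypic values and genetic variance for
    biallelic one- and two-locus models under Hardy-Weinberg and linkage
    equilibrium. Provides closed-form decompositions for the single-locus
    additive/dominance model and the two-locus additive-by-additive model, a
    general weighted least-squares partition of any 3x3 genotypic-value table
    into additive, dominance, additive-by-additive, additive-by-dominance and
    dominance-by-dominance components, Falconer-style partition tables of
    breeding values and dominance deviations, per-background dosage
    regressions, allele-frequency surface scans, and a forward population
    simulator demonstrating that GWAS dosage regression estimates the average
    effect of allele substitution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
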