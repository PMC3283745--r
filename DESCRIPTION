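Package: moirank
Title: Rank-Based Multiple Contrast Tests for Quantitative Traits with
    Unknown Mode of Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Nonparametric association testing between a di-allelic marker
    and a quantitative trait when the mode of inheritance is unknown.
    Estimates unweighted relative effects for the three genotype groups via
    pseudo-ranks, applies Marcus-type (dominant/additive/recessive) or
    all-pairs contrasts, and performs a max-T multiple contrast test with
    simultaneous confidence intervals (plain or Fisher range-preserving)
    and compatible adjusted p-values based on a multivariate t
    approximation.  Includes the pairwise-rankings variant with
    intransitivity detection, a two-locus linkage-disequilibrium
    genotype-phenotype simulator with variance-explained genotypic values,
    and comparator tests (Kruskal-Wallis, ANOVA, trend regression,
    parametric homo-/heteroscedastic multiple contrast tests) for type-I
    error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
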