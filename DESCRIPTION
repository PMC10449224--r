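Package: archaicx
Title: Sex-Biased Archaic Introgression Simulation and Chromosome X Coverage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of a single archaic introgression
    pulse into a recipient population with explicit sexes, autosomal or
    X-linked inheritance, purifying selection under a gamma distribution of
    fitness effects, and exact per-haplotype tracking of archaic ancestry
    tracts. Provides the coverage statistic (fraction of a haplotype in
    archaic tracts of at least 500 bp), the expected autosome to chromosome X
    haplotype ratio 2/(1+p) under introgressor female fraction p, bootstrap
    ratio estimation, purging timecourse summaries, tract-length spectra with
    a neutral exponential model, and an empirical pipeline for per-individual
    archaic tract calls (posterior and SNP-support filtering, pseudoautosomal
    exclusion, per-bp rates, outlier removal, group bootstrap summaries and
    Welch tests with Bonferroni correction). Includes synthetic-data
    generators for cohorts and neutral tracts so all analyses run without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    IRanges,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
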