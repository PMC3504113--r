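Package: strpopgen
Title: Population-Genetic Analysis of Forensic STR Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for worldwide population-genetic analysis of short tandem
    repeat (STR) marker data of the kind produced by forensic genetics:
    within-population diversity indices (unbiased expected heterozygosity,
    variance in repeat number) with rank-based group comparisons and
    Hardy-Weinberg testing; great-circle and waypoint-constrained geographic
    distances with diversity-versus-distance-from-origin regression;
    hierarchical analysis of molecular variance (AMOVA) under stepwise (R_ST)
    or identity (F_ST) allele-distance models, from genotypes or from allele
    frequencies alone, with permutation inference, multi-locus combination and
    Fisher's combined probability; pairwise R_ST matrices, Reynolds coancestry
    distances, nonmetric multidimensional scaling and Mantel tests; a
    marker-ascertainment experiment comparing heterozygosity-ranked locus
    panels; and forward-time serial-founder and Balding-Nichols generators of
    synthetic STR datasets for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    geosphere,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
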