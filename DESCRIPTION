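Package: admixqtl
Title: Cis-QTL Mapping, Colocalization and Ancestry Attribution in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping cis expression and methylation quantitative
    trait loci (QTLs) in admixed cohorts and attributing them to modern local
    ancestry or archaic introgression. Provides a permutation-based cis-QTL
    scan with genotype principal components and latent-factor covariates,
    Bayesian colocalization from summary statistics with multi-signal masking
    and prior-sensitivity classification, local-ancestry and archaic dosage
    regression (V = alpha x PAP + beta), interval-intersection filtering of
    archaic haplotype calls, the nSL haplotype selection statistic with
    frequency-bin normalization and windowed outlier tests, cross-dataset
    effect-size sharing and population-specificity classification, and
    matched-random-set annotation enrichment. Includes a synthetic admixed
    cohort generator (Balding-Nichols allele frequencies, Markov ancestry
    tracts, nested archaic segments, planted cis effects, latent-factor noise,
    external pseudo-cohorts) with ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
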