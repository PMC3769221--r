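Package: erap2hap
Title: Haplotype Structure and Compound-Genotype Analysis of the ERAP2 Locus
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for two-SNP and multi-SNP analysis of the
    ERAP2 locus in case-control cohorts: EM estimation of haplotype
    frequencies from unphased genotypes, pairwise linkage-disequilibrium
    statistics (D, D', r-squared), haplotype-block detection by the
    confidence-interval, four-gamete and solid-spine rules, compound-genotype
    observed-versus-expected testing, compound-homozygote detection power,
    Hardy-Weinberg and case-control association tests, SNP-SNP interaction
    (epistasis) testing by logistic regression, and phase-based prediction of
    ERAP2 protein and 392N variant expression. Includes a seeded synthetic
    cohort generator emulating the African-American and Chilean ERAP2
    haplotype structures so that every stage is testable without access to
    raw genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
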