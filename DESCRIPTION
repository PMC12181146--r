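Package: snpage
Title: Genome-Wide SNP-by-Age Interaction Scans for Cardiometabolic Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide gene-age interaction analysis (GWIS) of
    continuous cardiometabolic risk factors in biobank-style cohorts:
    phenotype preprocessing (medication corrections, log transformation,
    winsorization, complete-case filtering), per-variant linear interaction
    and marginal models with Wald tests, a streaming scan with minor-allele
    frequency filtering and Bonferroni thresholds, greedy linkage
    disequilibrium clumping of lead variants with positional gene mapping,
    two-stage look-up testing of marginal GWAS hits, and age- and
    sex-stratified genotype effect estimation. A synthetic biobank cohort
    generator with known genetic architecture (Hardy-Weinberg genotypes,
    tunable LD blocks, age and sex effects, medication masking) makes every
    stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
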