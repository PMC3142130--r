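Package: mrcox
Title: Mendelian Randomization for Biomarker-Disease Associations in
    Survival Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for judging whether the association between a serum
    biomarker and time-to-event outcomes is causal, using genetic variants
    as natural instruments.  Implements the three-stage Mendelian
    randomization design for cohort (survival) data: age- and sex-adjusted
    linear models of the log-transformed biomarker on genotype, Cox
    proportional hazards models of events on the biomarker and on
    genotype, and the expected-under-causality hazard ratio
    exp(beta_gm * beta_md) with Monte-Carlo confidence intervals obtained
    by propagating the two stage coefficients through one million
    pseudo-random draws.  Includes genotype quality control (minor allele
    frequency, Hardy-Weinberg chi-square test, two-locus EM linkage
    disequilibrium), stepwise multi-locus selection with cross-validated
    PRESS, a weighted allele score, a genotype-confounder screen, and a
    synthetic-cohort generator for testing every stage under causal,
    confounded and null scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
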