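Package: pairMHC
Title: MHC-Dependent Social Mate Choice Analysis for Translocated Bird Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether social pairing in small, male-biased bird
    cohorts depends on major histocompatibility complex (MHC) class I
    characteristics. Implements per-individual and per-dyad genetic metrics
    (MHC allele counts, allele-sharing Sxy, codon-masked amino-acid
    p-distance, standardized microsatellite heterozygosity, and
    Queller-Goodnight pairwise relatedness), a permutation engine that
    compares observed social pairs against all other possible male-female
    dyads using ANOVA-F and variance statistics (with an exhaustive
    enumeration oracle for small designs), a binomial logit model of male
    pairing status with Nagelkerke R-squared, per-allele Fisher exact tests
    with Bonferroni correction, and divorce analyses. A synthetic-cohort
    generator with configurable age, heterozygosity, MHC-diversity and
    MHC-compatibility effects makes the whole pipeline testable end to end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
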