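Package: polytrans
Title: Polygenic Scores and the Intergenerational Transmission of Education
Version: 0.1.0
Authors@R:
    person("Polytrans", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how much of the parent-child association in
    educational attainment is genetic and how much is social. Implements
    polygenic-score construction from GWAS weight tables, GCTA-compatible
    genomic-relatedness matrices with cryptic-relatedness pruning, single
    component AI-REML estimation of SNP heritability with a boundary
    likelihood-ratio test, family-cluster-robust regression suites with
    gene-environment and gene-gene interactions, within/between-family
    decomposition with sibling intraclass correlations, and the mediation
    scaling statistic that converts score-conditional attenuation of the
    parental-education coefficient into a genetic share of the
    intergenerational association. A forward simulator with assortative
    mating and Mendelian transmission generates two-generation cohorts whose
    moments match published estimates, so the whole pipeline is testable
    without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
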