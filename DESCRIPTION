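Package: admixlat
Title: Admixture, Geography, Phenotype and Self-Perceived Ancestry in
    Latin American Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for three-way (African/European/Native
    American) admixture analysis in Latin American cohorts: selection of
    ancestry-informative markers from candidate allele-frequency tables,
    supervised maximum-likelihood estimation of individual ancestry
    proportions with bootstrap standard errors, spatial analyses of
    ancestry (Moran's I and canonical-correlation permutation tests,
    ordinary kriging surfaces, census-size correlations), regression of
    physical-appearance phenotypes on ancestry with errors-in-variables
    correction, generalized Procrustes analysis of 3D facial landmarks,
    a banded self-perceived-ancestry bias statistic, and a polychoric
    principal-component wealth index. A synthetic-cohort generator
    emulating the statistical structure of such studies makes every
    stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    geosphere,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
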