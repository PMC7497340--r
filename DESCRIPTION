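Package: viGBLUP
Title: Genomic Analysis of Vegetation-Index Growth Curves in Hybrid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of multi-spectral
    vegetation-index (VI) phenotypes collected repeatedly over a growing
    season in hybrid crop trials. Computes standard vegetation indices
    (NDVI, GNDVI, NDRE, SAVI, EVI, simple Ratio) from plot-level band
    reflectances, builds VanRaden genomic relationship matrices for
    parental inbred panels and combines them into hybrid relationships,
    fits single-trait and bivariate GBLUP models by EM-REML (heritability,
    genetic and residual correlations, genomic prediction with a VI as a
    secondary trait), and fits linear-spline random-regression models of
    VI trajectories on a growing-degree-day time axis with
    covariance-function reconstruction between arbitrary time points.
    A synthetic-data module generates genotypes, pedigrees, weather, field
    layouts and longitudinal phenotypes with known variance structure so
    that every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
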