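Package: latentgwas
Title: GWAS and Downstream Genetic Analyses of Learned Imaging Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A desk-scale pipeline for imaging genetics: learn
    low-dimensional deep-network phenotypes from 3D brain volumes with a
    multi-task conditional variational autoencoder, reduce them by PCA,
    run covariate-adjusted genome-wide association scans with quality
    control and distance-based clumping, and carry the results through
    phenome-wide scans, voxel-wise statistical parametric maps, polygenic
    score comparison with a permutation test, and LD-score-regression
    heritability and genetic correlation.  A seeded synthetic-data module
    generates genotypes in linkage-disequilibrium blocks, template
    volumes with planted genetic effects, phenotype banks, and
    model-faithful summary statistics, so the whole pipeline is testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
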