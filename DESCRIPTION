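Package: dysconn
Title: Dysfunctional Connectome Analysis for Two-Group fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse group differences in resting-state functional
    connectivity (FC) between parcellated brain regions. Starting from
    per-subject ROI time series, the package computes Pearson FC matrices,
    screens edges by a cohort-wide correlation-magnitude criterion, tests
    each surviving edge for a group effect with linear regression adjusting
    for age and sex, and binarizes Bonferroni-significant edges into a
    signed dysfunction graph. Each dysfunctional edge is then classified as
    single-FC (triangle-free) or network-FC (triangle member), yielding
    per-region dysfunction ratios, hub-node structure over single-FC edges,
    and connected network-FC modules. Nodal local efficiency can be related
    to clinical scores by Pearson and partial correlation. A seeded
    synthetic cohort generator with implanted edge effects, covariates and
    clinical couplings supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
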