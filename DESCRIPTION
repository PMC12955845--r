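Package: hmivae
Title: Multi-View Conditional Variational Autoencoder for Highly Multiplexed Imaging
Version: 0.1.0
Authors@R: person("hmivae", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Derives four per-cell views from pixel-level highly multiplexed
    imaging data and segmentation masks (mean protein expression, protein
    nuclear co-localization, cell morphology, spatial context) together with
    technical covariates, learns integrated and view-specific latent
    representations with a multi-view conditional variational autoencoder,
    and supports downstream Leiden clustering, per-cluster feature ranking,
    cluster-prevalence summaries, clinical association by logistic
    regression, Cox proportional-hazards survival analysis, segmentation
    quality checks, and reference-to-query latent projection with KNN label
    transfer. Includes a synthetic-data generator emulating imaging mass
    cytometry acquisitions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    igraph,
    survival,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
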