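Package: noduleDRF
Title: Discriminative Random Field Segmentation of Lung Nodules in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic 3D segmentation of solid pulmonary nodules in
    chest CT volumes from a single seed point, using a discriminative random
    field over the voxel 6-neighbourhood graph: morphological estimation of
    nodule centre and radius, a logistic association potential over
    intensity and location features, an intensity-attenuated Ising
    interaction potential, simulated-annealing training of the potential
    weights on the training-set F-score, and exact binary MAP inference by
    min-cut/max-flow. Includes a synthetic CT phantom generator (spherical
    to lumpy nodules, juxtavascular and juxtapleural variants) so that
    training, inference and evaluation run end to end without clinical
    data, plus NIfTI and MetaImage volume I/O and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
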