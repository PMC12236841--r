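Package: cochleaquant
Title: Quantification of Cochlear Ribbon Synapses and Auditory Function Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cochlear synaptopathy studies: colocalized
    ribbon-synapse (CtBP2/GluA2) counting on maximum projections of confocal
    z-stacks, volumetric synapse analysis via Richardson-Lucy deconvolution and
    3D object segmentation with a voxel-size gate, auditory brainstem response
    (ABR) wave-1 and threshold extraction, distortion-product otoacoustic
    emission (DPOAE, 2f1-f2) measurement and thresholding, and a gated
    nonparametric/parametric group-comparison tree. Includes a synthetic-data
    generator that plants ground-truth synapses, evoked waveforms, ear-canal
    signals and cohort tables so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    withr,
    tibble,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
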