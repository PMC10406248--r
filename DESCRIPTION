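Package: strokewmh
Title: Stroke-Aware White Matter Hyperintensity Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Segmentation of white matter hyperintensities (WMH) on
    multi-modal brain MRI in the presence of stroke lesions. Implements a
    supervised k-nearest-neighbour voxel classifier with the full
    user-settings space (modalities, spatial weighting, intensity patches,
    training-point sampling policies, probability thresholds) and explicit
    stroke-lesion handling on classifier input or output; a distance-band
    adaptive-thresholding surrogate; an unsupervised Gaussian-mixture
    baseline segmenter; voxel-, cluster- and volume-level scoring (Dice
    similarity, false discovery/negative ratios, cluster-level error rates,
    detection and outline error rates, intraclass correlation of lesion
    volumes); a phased one-factor-at-a-time optimizer scored by
    leave-one-out cross-validation; and a cross-site validation experiment.
    A synthetic multi-site, multi-modal brain phantom generator with ground
    truth WMH, stroke, brain and ventricle masks makes every component
    testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
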