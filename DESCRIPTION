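Package: endoseg
Title: Segmentation and Supervised Evaluation of Corneal Endothelium
    Specular Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morphological segmentation of specular-microscopy images of
    the human corneal endothelium and supervised evaluation of the
    results. Provides three marker-controlled watershed pipelines built
    from mathematical-morphology operators (alternate sequential
    filtering, h-maxima, top-hats, openings by segments, skeleton
    pruning), a tolerance-aware dissimilarity criterion and Pratt's
    figure of merit for comparing contour maps against expert
    references, tolerance calibration from expert variability,
    grid-search learning of the pipelines' control parameters with
    K-fold cross-validation, clinical morphometry indices (endothelial
    cell density, polymegathism, pleomorphism), and a synthetic
    endothelium mosaic generator with paired ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
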