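Package: tubulometry
Title: Quantification of Dentinal Tubule Occlusion from Nano-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying silver occlusion of dentinal tubules in
    X-ray nano-computed tomography volumes of dentin specimens. Provides a
    synthetic conical dentin phantom generator with known ground truth,
    an optional parallel-beam projection and filtered back-projection
    stage, three-class threshold segmentation with contrast matching and
    median filtering, per-tubule morphometry (volume, bore diameter,
    orientation), and occlusion statistics: per-slice silver volume
    fraction depth profiles, silver-to-tubule volume percentage and
    penetration-depth quantiles. A command-line pipeline ties the stages
    together with deterministic, manifest-tracked outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
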