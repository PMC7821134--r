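Package: phasetree
Title: Quality-Guided Minimum-Spanning-Tree Unwrapping of MRI Phase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spatial unwrapping of 3D MRI phase volumes along a minimum
    spanning tree grown with a bucket priority queue, guided by per-edge
    quality maps combining spatial phase coherence, temporal phase coherence
    and magnitude coherence. Multi-echo and time-series (4D) data are
    unwrapped in a single step from one spatially unwrapped template volume
    under the assumption of linear phase evolution with echo time. Includes
    NIfTI input/output, conversion of unwrapped phase to B0 field maps, a
    synthetic wrapped-phase phantom generator with exact ground truth, and
    evaluation metrics (2-pi-multiple error counts, error histograms,
    temporal references, field-map standard deviation, global jump
    detection). A command-line interface exposes unwrapping, phantom
    generation and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
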