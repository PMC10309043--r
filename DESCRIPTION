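Package: emseg
Title: Semi-Automatic Membrane Segmentation Tools for Volume Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A scriptable pipeline for convolutional-network membrane
    segmentation of volume electron microscopy on commodity hardware:
    rotation-aware training-patch extraction from partially annotated
    ground truth, 2D U-net semantic segmentation with transfer-learning
    schedules (continuous learning, encoder freezing, leaky freeze,
    episodic memory), chunked tiled inference over filesystem tile-pyramid
    volumes with VSVI descriptor output compatible with the VAST
    annotation tool, watershed-based expansion of membrane probabilities
    into 2D instance segmentations, and variation-of-information scoring.
    Includes a synthetic cell-mosaic generator so every stage is testable
    without external data, and an ONNX reader/writer for model interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
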