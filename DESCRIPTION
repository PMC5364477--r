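Package: vesselchip
Title: Quantitative Imaging of the Endothelial Surface Layer and Red Blood
    Cell Flow in Microvessel-on-Chip Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for endothelialized microchannel imaging
    experiments. Measures the thickness of the endothelial surface layer
    (glycocalyx) from deconvolved 3D confocal stacks by full-width-at-half-
    maximum of cross-wall intensity profiles, extracts height maps and
    roughness statistics of the endothelial lumen surface, models laminar
    flow in rectangular ducts with an effective no-slip boundary, tracks
    flowing red blood cells in time-lapse stacks to build velocity profiles,
    and quantifies the near-wall cell-free layer, cross-stream cell
    distribution and in-channel hematocrit. A synthetic-data module
    generates ground-truth-labelled confocal and time-lapse stacks so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    pracma,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
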