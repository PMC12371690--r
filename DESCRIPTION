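Package: fibrilmap
Title: Fiber Width Quantification and Patch Classification for Fibrillar
    Network Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying interpenetrating fibrillar hydrogel
    networks from grayscale electron micrographs. Implements an automated
    fiber-width pipeline (intensity segmentation, exact Euclidean distance
    transform, topology-preserving skeletonization, centerline refinement,
    local width measurement and thin/medium/thick clustering) together with
    a sliding-window convolutional patch classifier that renders
    color-coded composition maps of amyloid-fiber versus polysaccharide
    regions. A synthetic fibrous-image generator with exact ground truth
    (centerlines, widths, class and region labels) makes every stage
    testable without access to the original micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
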