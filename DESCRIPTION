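Package: axontracer
Title: Automated Tracing and Length Quantification of Axons in
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless, batch-capable detection and quantification of labeled
    axons in RGB fluorescence microscope images of nervous tissue. Regions of
    interest (cell grafts, grey matter, manual polygons, or the whole frame)
    are segmented from a designated color channel by automatic contrast
    stretching, Otsu binarization, particle removal, hole filling and a
    distance-based enlarge/reduce sequence that merges fragmented signal into
    continuous regions. Axons inside the region are detected with inverted
    second-order Gaussian-scaled derivative (ridge) filters in x and y,
    binarized at a user-set sensitivity, reduced to one-pixel-wide topological
    skeletons, cleaned of small particles, and measured as total skeleton
    pixels, optionally normalized to the mean intensity of a reference region.
    A seeded synthetic-image generator provides fixtures with known analytic
    axon lengths, graft blobs, tissue holes and debris for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    EBImage,
    igraph,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'components.R'
    'morphology.R'
    'AllClasses.R'
    'imageIO.R'
    'polygon.R'
    'roiDetection.R'
    'skeleton.R'
    'tracing.R'
    'fixtures.R'
    'batch.R'
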