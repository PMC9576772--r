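Package: axoncyto
Title: White-Matter Axon Cytoarchitecture: Myelin Quantification, 3D
    Morphometry and In Silico Tissue Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative cytoarchitecture of white-matter fibre
    tracts from FIB-SEM image stacks. Implements a 2D myelin-content
    pipeline (median filtering, morphological background homogenisation,
    adaptive binarisation, white-pixel relative frequency), 3D axon
    morphometry on centerline-perpendicular measuring planes
    (cross-sectional area, best-fit diameter, fitted-ellipse ellipticity,
    tortuosity, axonal density, volume fraction), lognormal population
    statistics with mode/median extraction and an arithmetic-moment
    consistency check, and a generator of periodic in silico
    Representative Volume Elements of axon bundles matching tract-level
    statistics, exportable as watertight STL surface meshes. Includes
    synthetic FIB-SEM phantom generators (2D images and 3D labelled
    volumes) with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
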