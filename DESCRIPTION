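Package: coccimorph
Title: Morphometry of Coccoid Bacteria in Scanning Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing and morphometric analysis of instance-segmented
    bacterial cells in high-resolution scanning electron micrographs.
    Converts instance label masks into per-cell regions, fits ellipses by a
    direct least-squares conic method, removes segmentation artifacts and
    occluded background cells with a perimeter-distance neighbor filter,
    quantifies surface roughness as the residual of a second-order polynomial
    intensity detrend, and compares treatment groups with Cliff's delta
    effect sizes. Includes a synthetic micrograph generator with ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
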