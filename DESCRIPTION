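Package: fiberflow
Title: Flow-Aligned Collagen Fiber Orientation and Directed Spheroid Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the chain linking microfluidic channel flow to collagen
    fiber orientation and to directed invasion from a tumor spheroid: a
    depth-averaged (Hele-Shaw) potential flow around an immobilized spheroid,
    slender-rod advection producing the fiber orientation field, an
    anisotropic four-move random-walk invasion simulator driven by that
    field, and quantification statistics (degree of alignment from
    orientation histograms, sector-wise invasion-front distances, and a
    perpendicular-step-size sweep). Includes a synthetic fiber-image
    generator and a local-gradient orientation estimator so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    deSolve,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
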