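Package: biliflow
Title: Canalicular Bile Pressure Modelling and Zone-Resolved Network
    Morphometry for the Liver Lobule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves the radially symmetric osmotic/Darcy bile-pressure
    boundary-value problem of the liver lobule by a shooting method and
    quantifies skeletonized bile-canaliculi networks along the central
    vein to portal vein (CV-PV) axis: zone-resolved radius, volume
    fraction, surface-to-volume, connectivity, branch crossings and
    junction density; detection and volume estimation of liver cell
    rosettes (dilated lumina wider than 6 um bounded by more than two
    hepatocytes) in 3D reconstructions and 2D sections;
    marker-positivity classification; and the correlation and
    group-comparison stage linking rosette burden to predicted
    canalicular pressure. Ships a seeded synthetic-data generator
    emulating control and cholestatic (PSC-like) lobules so the whole
    pipeline runs end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
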