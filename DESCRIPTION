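Package: vasodose
Title: Multiscale Vascular Dosimetry of the Liver
Version: 0.1.0
Authors@R:
    person("vasodose", "maintainers", email = "maintainers@vasodose.dev",
           role = c("aut", "cre"))
Description: Tools for multiscale internal dosimetry of vascularized organs,
    with the liver as the reference application. Generates synthetic
    macroscale vascular centerline trees under Murray's law inside an organ
    boundary, converts them to watertight surface meshes, builds a stylized
    hexagonal-prism hepatic lobule (sinusoids, central vein, portal triads,
    bile channels, space of Disse, Kupffer cells), samples labeled
    tetrahedral meshes barycentrically, runs a simplified desk-scale particle
    transport to estimate absorbed fractions with escape or reflective
    boundaries, couples macroscale and microscale absorbed fractions into
    blood and parenchyma specific absorbed fractions, and computes
    radionuclide S-values under the MIRD schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
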