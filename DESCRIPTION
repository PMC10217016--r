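Package: demintrack
Title: Time-Lapse Micro-CT Quantification of Enamel Demineralisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the progression of acid demineralisation
    in dental enamel from time-lapse 3D tomography. Each tomogram in a time
    series is denoised, rigidly registered to a reference time point and
    segmented; the demineralised lesion is then summarised by per-angle
    radial front distances, per-slice areas, lesion volumes and their
    normalisations and rates (micrometres, square and cubic micrometres per
    second). A synthetic dissolving-enamel phantom with a hexagonal rod
    lattice, a surface zone and per-material front speeds provides ground
    truth for end-to-end validation, including anisotropic propagation in
    which the inter-rod substance dissolves faster than the rods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
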