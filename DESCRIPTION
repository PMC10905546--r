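Package: tumorflow
Title: Tumor Tissue Hydraulic Conductivity, Interstitial Fluid Flow and
    Drug Penetration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the hydraulic conductivity (K) of tumor
    tissue from Ussing-chamber bubble-tracking measurements, relating K to
    tumor-microenvironment composition (collagen fiber, cancer cell and
    fibroblast area densities) by simple linear regression, and simulating
    the downstream consequences for drug delivery: steady interstitial
    fluid pressure and velocity from Darcy flow with Starling transvascular
    exchange and lymphatic drainage, and transient interstitial drug
    concentration by advection-diffusion with transvascular exchange, on a
    spherically symmetric three-region tumor (necrotic core, hypoxic shell,
    viable rim) embedded in normal tissue. Includes a synthetic-data
    generator with known ground truth for every pipeline stage and a
    parameter-study driver for homogeneous and heterogeneous radial K maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
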