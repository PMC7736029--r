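Package: spraydry
Title: Data-Driven Spray-Drying Process Development for Peptide Isolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lab-scale spray-drying process development of
    peptide and sugar formulations. Implements psychrometric moist-air
    bookkeeping and an evaporative heat/mass balance for an open-loop
    dryer, Gordon-Taylor glass-transition prediction with GAB moisture
    sorption and a stickiness-curve design space, single-droplet drying
    analysis (d2-law evaporation rate, lock point, Peclet number,
    surface enrichment, solute diffusivity), 3D voxel morphology
    descriptors (sphericity, solidity, convexity, solid-phase density),
    and powder quality-control metrics (thermogravimetric residual
    moisture, dihydrate content, vacuum-drying removal, volume-weighted
    particle-size quantiles and Hartigan dip-test agglomeration
    scoring). Seeded synthetic-data generators emulate every input so
    the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    quadprog
Config/testthat/edition: 3
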