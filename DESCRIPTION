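Package: porefield
Title: Finite-Element Simulation of Nanotube-Enhanced Cell Electroporation
    by Nanosecond Pulsed Electric Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain quasi-static finite-element simulation of a single
    five-layer dielectric cell (extracellular medium, plasma membrane,
    cytoplasm, nuclear envelope, nucleoplasm) exposed to a nanosecond pulsed
    electric field, with randomly placed high-aspect-ratio conductive carbon
    nanotube (CNT) capsules sampled by Monte Carlo rejection. Both membranes
    are represented as zero-thickness distributed-impedance interfaces whose
    normal current carries conduction, displacement and electroporation
    terms; per-node pore density follows the asymptotic Smoluchowski-derived
    rate equation and a representative pore radius evolves by the pore-energy
    gradient. Post-processing provides field-strength area histograms,
    electroporated membrane area, permeabilized flux, and analytic
    diagnostics (Schwan transmembrane voltage, tip field enhancement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deldir,
    RANN,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    polyclip,
    sp,
    withr,
    optparse
Config/testthat/edition: 3
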