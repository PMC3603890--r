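Package: celltransit
Title: Reduced-Order Simulation of Neutrophil Transit Through Constricted
    Microchannels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the passage of a neutrophil through a moderately
    constricted microchannel, either an axisymmetric arc-shaped capillary
    or a rectangular channel whose side walls carry arc-shaped
    constrictions.  The cell is a Maxwell liquid drop with a constant
    cortical tension; transit is integrated with a quasi-static lumped
    scheme in which creep of the cell interior under the wall reaction
    stress limits the advance of the cell, and plasma leakage through the
    corner gutters of the rectangular lumen reduces the pressure drop that
    drives it.  Exact channel geometry (imaginary-wall offset surfaces,
    squeeze length, contact angle, hydraulic-diameter matching), corner
    leakage hydraulics, parameter sweeps over channel height, throat width
    and constriction curvature radius, and power-law scaling fits of the
    transit time are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
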