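Package: stentflow
Title: Hydraulic Network Model of Urinary Flow in the Stented Ureter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Reduced-order simulator of steady laminar urine drainage through
    a ureter fitted with a double-J stent whose wall may be porous.  The
    stented ureter is discretised into a resistor network of laminar
    conductances (Hagen-Poiseuille pipe, concentric annulus, Sampson side
    hole, radial Darcy wall) and solved for nodal pressures and compartmental
    mass flow rates.  Includes nine reference case studies (permeability
    sweep, no-side-hole stent, complete mid-ureter occlusion), per-segment
    intraluminal/extraluminal flow decomposition, side-hole activity
    analysis, permeability sweeps and inversion of wall permeability from an
    observed drainage rate.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    tools,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
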