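Package: wkcalib
Title: Calibration of Three-Element Windkessel Outlet Boundary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order tools for prescribing patient-specific outlet
    boundary conditions in cardiovascular models. Estimates three-element
    Windkessel (impedance-resistance-compliance) parameters for each branch
    of the thoracic aorta from vessel geometry and pulse wave velocity,
    simulates the 0D Windkessel model by backward Euler in both causalities
    (pressure from flow and flow from pressure), generates periodic branch
    pressure waveforms with a lumped RLC arterial-tree model, calibrates the
    parameters against measured branch flow waveforms (such as those derived
    from 4D Flow-MRI) by Nelder-Mead least-squares fitting, and computes
    hemodynamic summary metrics: time-averaged wall shear stress, oscillatory
    shear index, pressure summaries, perfusion fractions, and pulse wave
    velocity from multi-plane waveforms. Includes seeded synthetic generators
    for every input so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
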