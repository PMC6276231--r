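Package: lvadsim
Title: Multi-Scale Hemodynamic Simulation of Rotary Blood Pump Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop multi-scale model of the human circulation under
    left ventricular assist device (LVAD) support. Intracellular calcium
    transients drive troponin/cross-bridge kinetics in the left-ventricular
    wall; a hemispherical Laplace-law chamber maps sarcomere force to
    pressure inside an eight-compartment lumped circulation with four
    valves and a rotary intra-aortic blood pump. Provides periodic
    steady-state integration, pump speed control (constant, co-pulse and
    counter-pulse modulation), blood assist index (BAI) and mean arterial
    pressure targeting, evaluation indices (ventricular external work,
    pulsatile ratio, pressure-volume loops), baseline calibration, and
    scenario runners for support-level sweeps, support-mode comparisons
    and beta-blocker coupling experiments.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
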