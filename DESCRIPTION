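Package: betaburst
Title: Integrated Oscillator Model of Pancreatic Beta-Cell Electrical and
    Metabolic Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the Integrated Oscillator Model (IOM) of the pancreatic
    beta-cell: a stiff ODE system coupling membrane electrical activity and
    Ca2+ handling, an allosteric-phosphofructokinase glycolytic oscillator,
    and a reduced mitochondrial bioenergetics module.  Provides declarative
    in-silico protocols (diazoxide, KCl depolarization, cytosolic Ca2+ clamp,
    glucose steps), an oscillation-analysis layer that detects bursts and
    burst episodes and classifies metabolic oscillations as passive (PMO,
    Ca2+-driven) or active (AMO, intrinsic glycolytic), and preset scenarios
    for the canonical oscillatory regimes (slow bursting, compound bursting,
    subthreshold metabolic oscillations, mitochondrial membrane-potential
    phase reversal).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
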