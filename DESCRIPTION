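Package: cardioloop
Title: Closed-Loop Lumped-Parameter Haemodynamics with VA-ECMO and IABP Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) simulation of the human
    circulation built from time-varying elastance heart chambers with septal
    interaction, an RLC systemic/pulmonary vessel network with an RC coronary
    branch, and models of two mechanical circulatory support devices:
    veno-arterial extracorporeal membrane oxygenation (central or peripheral
    cannulation, centrifugal pump head curve) and the intra-aortic balloon pump
    (pneumatic drive/vacuum source with gas delivery resistance). Includes a
    deterministic tuner that produces a cardiogenic-shock baseline satisfying
    standard haemodynamic criteria, a full haemodynamic and pressure-volume
    energetic metric suite (external work, pressure-volume area, effective
    arterial elastance, ventricular-arterial coupling), and a study pipeline
    that runs the support-condition matrix and reports percentage changes
    against the pathological baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
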