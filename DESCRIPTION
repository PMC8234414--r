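Package: clotforce
Title: Force Transduction and Myosin Light Chain Phosphorylation Analysis
    for a MEMS Clot Contraction Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing platelet clot-contraction force measured with a
    silicon torsion-beam microelectromechanical (MEMS) sensor, and for relating
    that force to myosin light chain (MLC) phosphorylation. Implements the
    torsion-beam suspension model (rectangular-section torsional constant,
    effective platform spring constant, Hooke's-law force transduction,
    nanoindenter calibration linearity), a displacement-to-force contraction
    pipeline with kinetic summaries, in-cell ELISA pMLC normalisation and
    percent-change statistics, a signed directed-graph model of the MLCK/MLCP
    signalling cascade with perturbation-direction prediction, and a synthetic
    data generator that emulates contraction traces, calibration series, ELISA
    plates and blot lanes so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
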