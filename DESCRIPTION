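Package: flowdiv
Title: Estimating Branch Flow Division in Diseased Aortas with 0D Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating patient-specific flow division in the
    branches of a diseased aorta when measured branch flow rates are
    unavailable. A lumped-parameter (0D) nonlinear network solver acts as the
    hemodynamic forward model on synthetic aortic trees carrying ostial
    stenoses, fusiform aneurysms, or dissections with true/false lumina. The
    package implements empirical healthy-subject flow-division rules,
    brachial-to-aortic pressure conversion, conversion of reference-model
    pressures into outlet resistances, and an iterative loop that adjusts the
    reference mean pressure until the diseased model reproduces the target
    inlet pressure. Downstream utilities tune three-element Windkessel outlet
    models, run transient backward-Euler simulations over several cardiac
    cycles, and compute wall-shear and flow metrics (TAWSS, OSI, RRT, AFI,
    local normalized helicity, transmural pressure).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
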