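Package: cordsim
Title: Tumour-Cord Pharmacodynamics with Switch-Based Apoptosis Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for the action of an anti-cancer drug (parameterized
    for doxorubicin) on a cylindrical tumour cord. Couples interstitial
    free/bound drug transport with a Kedem-Katchalsky transcapillary boundary
    condition, cellular drug uptake and efflux, intracellular apoptosis
    signalling represented by either a monostable Hill switch with an
    irreversible downstream effector or a bistable positive-feedback switch,
    and logistic tumour-cell population dynamics. Includes steady-state and
    saddle-node bifurcation analysis of the signalling modules, a library of
    dosing-protocol scenarios (constant infusion, single and repeated bolus,
    fractionation), and kill-zone summary metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
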