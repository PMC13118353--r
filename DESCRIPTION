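Package: ocutmdd
Title: Ocular PBPK-PD Simulation of Anti-TNF-alpha Antibodies in Anterior Uveitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of tumour necrosis factor alpha (TNF-alpha)
    kinetics in the anterior chamber and iris-ciliary body of uveitis-diseased
    rats under intravenous multiple-dose and intravitreal sustained-release
    dosing of anti-TNF-alpha monoclonal antibodies. Implements a reduced
    five-compartment ocular/systemic disposition model with full
    target-mediated drug disposition (TMDD), complex-fraction-driven recovery
    of diseased ocular flows, event-driven stiff ODE integration, endpoint
    metrics (average percent reduction in free TNF-alpha, fold changes, outcome
    classification), model-informed design of intravitreal zero-order release
    devices against a 90 percent TNF-alpha reduction objective,
    device-emptying failure analysis, and synthetic-observation generation
    with parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
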