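Package: dvtcostmin
Title: Cost-Minimization Modeling of Deep Venous Thrombosis Diagnostic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cost-minimization model comparing two diagnostic
    pathways for suspected lower-extremity deep venous thrombosis (DVT):
    referral to a hospital emergency department for radiologist-performed
    ultrasound versus limited compression ultrasound (LCUS) performed by
    general practitioners in primary health care. Provides a validated
    configuration layer for unit costs, time assumptions, pathway counts and
    training parameters; a synthetic patient-cohort generator and
    standardized-patient construction; eight-component per-patient cost
    breakdowns with payer (public/private) and direct/indirect
    classification; a real-life mixture scenario with one-time training
    costs and first-year budget impact; and paired Student-t comparison of
    per-patient costs with confidence intervals. All monetized time uses the
    human capital approach.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
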