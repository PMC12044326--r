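Package: pbpkddi
Title: Minimal Physiologically Based Pharmacokinetic Modeling of Drug-Drug
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation of drug-drug interaction (DDI) liability
    with a minimal physiologically based pharmacokinetic (PBPK) model: gut
    lumen, enterocyte, liver, systemic and single-adjusting compartments,
    per-isoform linear and Michaelis-Menten intrinsic clearances, competitive
    enzyme and transporter inhibition, and turnover-based enzyme induction.
    Includes retrograde derivation of intrinsic clearance from observed
    systemic clearance, Caco-2 to jejunal-permeability calibration, the Qgut
    intestinal first-pass model, virtual healthy-volunteer populations,
    non-compartmental analysis, and geometric-mean-ratio trial statistics,
    together with a validated compound-file format and a packaged compound
    library centred on the cholesterol 24-hydroxylase inhibitor soticlestat.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
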