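Package: pbpktgi
Title: Whole-Body PBPK and Tumor Growth Inhibition Modelling of MBQ-167 in
    Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) and
    pharmacodynamic modelling of the Rac/Cdc42 inhibitor MBQ-167 in mice.
    Implements a whole-body perfusion-limited PBPK model with lagged
    first-order intraperitoneal absorption into venous blood, well-stirred
    hepatic elimination scaled from in vitro hepatocyte intrinsic
    clearance, glomerular-filtration renal elimination, Rodgers-Rowland
    (method 2) tissue-to-plasma partition coefficient prediction, and a
    permeability-limited tumor compartment with efflux transport.  Couples
    the plasma profile to Simeoni tumor growth inhibition models with a
    configurable transit chain for HER2+ and Triple Negative breast cancer
    xenografts.  Includes non-compartmental analysis, weighted
    least-squares Nelder-Mead parameter estimation, local sensitivity
    analysis, dosing-regimen exploration and synthetic study-data
    generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
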