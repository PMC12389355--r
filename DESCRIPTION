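Package: cypind
Title: CYP Induction Drug-Drug Interaction Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative assessment of cytochrome P450
    induction-mediated drug-drug interactions (DDIs) from in vitro
    hepatocyte triculture concentration-response data. Fits sigmoidal
    Emax/EC50 induction curves with the regulatory <2-fold no-call rule,
    evaluates the ICH M12 basic mechanistic static model (R3) with
    fraction-metabolized (fm) weighting across enzymes, and runs a minimal
    dynamic enzyme-turnover PBPK simulator in which multiple-dose
    perpetrator pharmacokinetics drive per-enzyme synthesis/degradation
    (kdeg) dynamics and fm-partitioned well-stirred hepatic clearance of
    the victim drug. Ships a typed registry of induction parameters,
    fraction-metabolized maps and literature base-PK fixtures for
    rifampicin and common CYP3A4/CYP2C victim drugs, synthetic-data
    generators for end-to-end testing, and reporting helpers that classify
    predicted AUC ratios against the 0.8-1.25 bioequivalence and 0.5-2.0
    no-DDI bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
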