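Package: mmrscreen
Title: Simulation and Evaluation of Automated Mismatch-Repair IHC Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for developing and stress-testing automated scoring of
    DNA mismatch-repair (MMR) immunohistochemistry on tissue microarrays.
    Provides a synthetic cohort generator with the case-core-cell hierarchy,
    heterodimer expression correlation and staining-failure modes of large
    adjuvant colorectal-cancer trial cohorts; a brightfield H-DAB core image
    simulator with per-nucleus ground truth and a classical (colour
    deconvolution, watershed) single-cell caller; quality-control and
    case-level MMR scoring including the minimum percent-positive statistic;
    diagnostic evaluation (AUROC with bootstrap, Youden and fixed-sensitivity
    threshold calibration, rule-out extrapolation, Cohen's kappa and Gwet AC1
    agreement, MSI cross-tabulation); and recurrence-free-interval survival
    analysis with Cox interaction power simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
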