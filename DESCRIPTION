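Package: mapkdual
Title: Mass-Action Modeling of Dual MEK/ERK Inhibition and
    Drug-Combination Synergy Analysis
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Mass-action kinetics model of the RAS-RAF-MEK-ERK signaling
    cascade with three canonical negative feedbacks (ERK-mediated
    inhibitory phosphorylation of CRAF and MEK, DUSP-catalyzed ERK
    dephosphorylation, and SPRY inhibition of Grb2-SOS-driven RAS
    activation), reversible binding pharmacology for MEK and ERK
    inhibitors, and the downstream analysis toolkit for drug-combination
    studies: four-parameter logistic dose-response fitting with robust
    outlier handling and GI50 extraction, Loewe-additivity and
    Bliss-independence expectation surfaces, isobologram extraction,
    excess-based synergy scoring with a sham-combination control,
    pathway-reactivation metrics, and in-vivo efficacy metrics (percent
    tumor growth inhibition from fitted exponential growth curves and
    progression-free survival from tumor doubling). Includes synthetic
    data generators for dose-response curves, combination matrices and
    xenograft cohorts so every analysis stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    survival,
    yaml,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
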