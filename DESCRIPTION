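Package: kickout
Title: Kick-Out Model of dCas9-Mediated Transcriptional Repression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling and analysis of CRISPR interference
    (CRISPRi) in bacteria under the kick-out mechanism, in which RNA
    polymerase ejects promoter-proximal dCas9 roadblocks during successful
    transcription events.  Provides the analytic steady-state model of
    relative expression and parameter inference from measured knockdown,
    bounds on spontaneous dCas9 unbinding and complex lifetime, an exact
    stochastic (Gillespie) single-cell simulator of expression noise under
    complementarity- versus concentration-tuned repression, steady-state
    inference for a Hill-type auto-repressor feedback loop, single-cell
    cytometry statistics (outlier trimming, blank correction, noise
    decomposition, log-scale significance tests, doubling-time fits),
    cell-contour morphometrics, and synthetic-data generators that emulate
    flow/imaging-cytometry measurements for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
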