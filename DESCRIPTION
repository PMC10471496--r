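Package: optoprop
Title: Analysis of Targeted Photostimulation Propagation Through Cortical Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing all-optical experiments in which groups of
    cortical neurons are photostimulated while two-photon calcium imaging
    records local (S1) and downstream (S2) population activity and the animal
    reports perception by licking. Implements the full analysis chain:
    neuropil-corrected dF/F preprocessing with photostimulation blanking,
    signal-detection behavioural analysis (d-prime, psychometric fits),
    pre-stimulus population metrics and a signal-to-noise logistic model of
    trial outcome, effective-recurrence inference from the width of the
    non-shared cross-covariance distribution, network response timescale
    estimation from targeted-cell decay, time-resolved population decoding,
    and excitation-inhibition balance statistics. Ships a synthetic-session
    generator (linear recurrent network, shared latent input, Poisson spiking,
    GCaMP6s-like fluorescence rendering) so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rhdf5,
    glmnet,
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
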