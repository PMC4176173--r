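Package: polqueue
Title: Stochastic Modelling of RNA Polymerase Queuing, Elongation Kinetics
    and Transcription Fidelity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of transcription elongation as a
    one-dimensional exclusion process of extended RNA polymerase complexes
    with stochastic long-lived pauses and rescue, as used to study
    Gre-factor-dependent transcription in Streptococcus pneumoniae. Includes
    virtual induction (two-probe) experiments with an onset-based elongation
    velocity estimator, steady-state transcription-rate sweeps over
    initiation rate and gene length, queue ("traffic jam") statistics, a
    synthetic FASTQ read generator with independent transcription,
    reverse-transcription and sequencing error channels, and a
    filter/map/tally pipeline that estimates per-base mismatch rates against
    a reference sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
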