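Package: scrunchFRET
Title: Kinetic Analysis of Transcription Initiation Pausing from Single-Molecule FRET Trajectories
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule FRET trajectories of bacterial
    transcription initiation: FRET efficiency computation and trace selection,
    Gaussian-emission hidden Markov segmentation with an Allan-deviation step
    filter, pooling of state dwell times, multi-exponential dwell-time maximum
    likelihood fits with BIC model selection and bootstrap uncertainties,
    NTP-dependent pause-escape isotherm fitting, trajectory pathway
    classification, and a Gillespie simulator of the branching kinetic scheme
    (initial-transcription pause, productive escape, unscrunching/scrunching
    cycling) so that every analysis stage can be validated by parameter
    recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'branch.R'
    'dwell.R'
    'fret.R'
    'gillespie.R'
    'hmm.R'
    'io.R'
    'pipeline.R'
    'render.R'
    'scheme.R'
    'stepfilter.R'
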