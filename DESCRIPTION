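Package: simonfmri
Title: Simulation and Analysis of Simon-Task fMRI Studies of Conflict
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for event-related
    Simon-task fMRI studies of cognitive conflict: sequence-dependent
    trial coding (cC/cI/iC/iI), behavioral repeated-measures analysis,
    first-level general linear models with canonical double-gamma
    hemodynamic convolution and discrete-cosine high-pass confounds,
    covariate-adjusted random-effects group inference with Monte-Carlo
    cluster-extent familywise correction, within-group severity
    correlation, and seed-sphere Granger Causality Index connectivity.
    A synthetic-cohort generator produces task designs, behavioral
    records and 4D BOLD volumes with known ground truth, so every stage
    of the analysis is exercised without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
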