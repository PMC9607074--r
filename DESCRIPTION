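Package: adtrca
Title: Adaptive Task-Related Component Analysis for SSVEP Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency recognition for steady-state visual evoked potential
    (SSVEP) brain-computer interfaces. Implements adaptive task-related
    component analysis (adTRCA): a class-specific temporal smoothing filter is
    learned by multi-task sparse Bayesian linear regression on a dictionary of
    stimulus harmonics, and combined with a generalized-eigenvalue spatial
    filter; canonical correlation analysis (CCA) and task-related component
    analysis (TRCA) baselines and their ensemble variants are included, along
    with a synthetic SSVEP generator, leave-one-block-out cross-validation,
    accuracy and information-transfer-rate metrics, and a small command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
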