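Package: neurobridge
Title: Multiscale Analysis Linking Synaptic Density, EEG Spectra and
    Brain-Cognition Signatures in Schizophrenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiscale computational psychiatry analyses:
    sparse partial least squares (SPLS) extraction of brain-cognition
    signatures with permutation testing, resting-state EEG band-power
    statistics with FDR-controlled nonparametric group comparison,
    nested cross-validated linear support-vector regression for
    cross-modal prediction, and a reverse-personalized canonical
    microcircuit neural mass model that maps per-subject synaptic
    density onto simulated EEG power spectra. A synthetic multimodal
    cohort generator with planted ground truth makes every stage
    testable end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
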