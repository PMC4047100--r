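Package: sahpkit
Title: Current-Clamp Sweep Analysis of Medium and Slow After-Hyperpolarizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trace-to-statistics analysis of current-clamp recordings from
    pyramidal neurons: passive membrane property estimation from a
    hyperpolarizing probe, spike detection and waveform feature extraction,
    bi-exponential decomposition of the post-step after-hyperpolarization
    (AHP) into medium and slow components by constrained Nelder-Mead fitting,
    and two-group inference on AHP amplitudes with linear mixed-effects
    models, likelihood-ratio tests, influence screening, multiple imputation
    by expectation-maximization with bootstrapping, and simulation-based
    power analysis. Includes a synthetic-trace generator with exact ground
    truth so the whole pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    MASS,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
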