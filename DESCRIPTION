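Package: ansflow
Title: Autonomic Function Evaluation from Bilateral Blood-Flow Coherence,
    Heart Rate Variability and Electrogastrography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating autonomic nervous system (ANS) function
    from peripheral physiological signals. Implements Welch
    magnitude-squared coherence of bilateral laser-Doppler skin blood
    perfusion recordings with extraction of the cardiac-band peak
    frequency (PF), time-domain and Poincare heart rate variability
    metrics with smoothness-priors detrending and composite
    parasympathetic/sympathetic indices (PNSi/SNSi), electrogastrogram
    dominant-frequency estimation, and the statistical layer linking PF
    to the autonomic indices (Spearman correlation with FDR correction,
    frequency-wise group comparison with cluster labelling, linear
    regression and external-prediction validation). Seedable synthetic
    generators emulate the statistical structure of each signal so the
    whole pipeline is testable without access to recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    signal,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
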