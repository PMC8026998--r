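Package: retinakit
Title: Light-Response Electrophysiology, Cone-Survival Kinetics and
    Expression Statistics for Retinal Neuroprotection Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolbox for quantifying photoreceptor
    neuroprotection in rodent models of retinal degeneration. Implements
    a micro-electrode-array (MEA) light-response pipeline (Butterworth
    band-pass filtering, threshold-based spike detection with a refractory
    pause, stimulus-windowed spike counting, paired-t light-activation
    classification and a Michelson-style response ratio with rank-sum
    group comparison), log2-linear exponential-decay fitting of cone
    survival with x-intercept extrapolation and shared-control Hedges' g
    estimation (BCa bootstrap and permutation inference), and expression
    statistics (counts-per-million filtering, permutation-FDR t tests and
    delta-delta-CT qPCR fold changes). Ships seeded synthetic-data
    generators for every input so the full pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
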