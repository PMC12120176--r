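Package: pp3bp4
Title: Calibration of Computational Evidence Strengths for Missense Variant
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates computational scores (AlphaMissense-style pathogenicity
    scores, FoldX-style folding stability changes, meta-predictor scores) into
    ACMG/AMP PP3/BP4 evidence strengths for missense variants, using multiplexed
    assay of variant effect (MAVE) functional classes as truth proxies. Provides
    three-zone likelihood ratios with confidence intervals, point-based evidence
    strength mapping, threshold search, stratification by relative solvent
    accessibility and functional domain, cascade evidence assignment, diagnostic
    test evaluation, case-control burden odds ratios, and a synthetic cohort
    generator emulating the statistical structure of a saturation MAVE dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
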