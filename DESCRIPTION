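Package: mefahrv
Title: Multilevel Factor Analysis of Heart-Rate-Variability Indices over Exercise Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for deriving autonomic indicators from RR-interval tachograms
    recorded over the epochs of a dynamic exercise protocol. Computes a panel of
    twelve heart-rate-variability proxies (time-domain statistics, autoregressive
    spectral band powers, phase-rectified signal averaging, symbolic dynamics and
    a conditional-entropy regularity index), decomposes the panel into
    between-subject and within-subject latent factors via two-level exploratory
    factor analysis, re-expresses factor scores as indicators on the [0, 100]
    scale through the cumulative distribution of a kernel density estimate, and
    provides the accompanying non-parametric inference battery (rank-based
    ANOVA-type tests for longitudinal data, permutation and bootstrap two-sample
    tests, FDR adjustment), stratified balanced bootstrap with BCa intervals,
    and heatmap-style reporting. A synthetic-study generator with a known
    two-level factor structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
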