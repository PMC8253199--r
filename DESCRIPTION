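Package: phosnet
Title: Panel Granger Causality Networks for Phosphorus-Regulation Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed regulatory networks from short balanced panel
    time series of physiological analytes (serum phosphate, corrected calcium,
    PTH, FGF23, alpha-Klotho, 1,25-dihydroxyvitamin D, BALP, urinary Pi/Cr)
    measured repeatedly in a small subject cohort under dietary phosphate
    interventions. Provides a Levin-Lin-Chu panel unit-root screen with
    runtime-calibrated adjustment moments, pairwise panel Granger causality
    with fixed-effects within transformation and half-panel jackknife bias
    correction, weighted-adjacency network construction with degree,
    betweenness and density metrics, repeated-measures correlation and
    Kruskal-Wallis companion statistics, and a panel-VAR synthetic data
    generator with known causal ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
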