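Package: vwmdecode
Title: Cross-Decoding of Perception and Visual Working Memory from fMRI
    Surface Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether perception and visual working memory
    (VWM) share a neural representation, using multivariate cross-decoding of
    cortical-surface fMRI response patterns.  The package implements the full
    analysis chain: a 16-condition delayed match-to-sample design with
    distractor streams during the memory delay; a synthetic vertex time-series
    generator whose perceptual and memory population codes can be identical,
    partially rotated, or orthogonal; finite impulse response (FIR) beta-series
    estimation with an odd/even run split and leave-one-run-out run
    combinations; matched-condition within- and cross-decoding with linear
    support vector machines and the cross-decoding ratio statistic; and a
    group-level battery of one-tailed and paired t tests with
    Benjamini-Hochberg correction plus two-way repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
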