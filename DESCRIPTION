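Package: alfibril
Title: Worm-Like-Chain Mechanics and Core Geometry of Amyloid Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of ex vivo amyloid fibrils traced as 3D
    polygonal chains. Provides a discrete worm-like-chain simulator with
    known persistence length, per-fibril contour-length and end-to-end
    geometry, nonlinear least-squares estimation of the persistence length
    from the Kratky-Porod mean squared end-to-end relation with linearized
    or bootstrap confidence intervals, bending-rigidity conversion,
    helical-parameter arithmetic (rise, twist, pitch, crossover distance,
    handedness), a five-predictor consensus aggregation score with
    segment calling, and ordered-core/mutation-mapping statistics for
    fibril structures, including a Gill-von Hippel extinction-coefficient
    utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
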