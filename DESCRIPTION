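Package: rootmeristem
Title: Single-Cell Geometry, Kinematics and Radial Growth Mechanics of the
    Root Meristem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline linking the three-dimensional geometry of
    single cells in the Arabidopsis root meristem to whole-organ radial
    growth under varying brassinosteroid (BR) signalling. Provides
    seeded synthetic-data generators for per-cell geometry tables,
    time-lapse displacement tracks, lineage-tracked two-time-point (4D)
    cell pairs and polygonal root cross-section meshes; a two-Gaussian
    mixture classifier separating meristem from elongation-zone cells by
    cell length; mixed-model analysis of transformed geometry parameters
    with Tukey post-hoc tests, a two-step adaptive false-discovery-rate
    correction and a percent-variance-explained statistic; root
    growth kinematics (displacement-rate regression, meristem residence
    times, production-rate bookkeeping); per-cell directional growth rates
    in 4D with ANCOVA; and a mass-spring simulator of a growing root
    cross section with wall-class stiffness, tissue extensibility, and a
    two-multiplier inner/outer stiffness fitting procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    multcomp,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
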