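Package: vrfmed
Title: Vascular Risk Scores, Voxel-Wise Gray-Matter Statistics and
    Bootstrap Mediation
Version: 0.1.0
Authors@R:
    person("VRFMED", "Maintainers", email = "maintainers@vrfmed.invalid",
           role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline linking a composite
    vascular-risk-factor (VRF) score to cortical gray-matter atrophy and
    cognitive decline: binarization and relative-risk weighting of six
    vascular risk factors, cohort-level group statistics and partial
    correlations, mass-univariate linear models and ANCOVA on gray-matter
    volume images, Monte-Carlo cluster-extent correction with residual
    smoothness estimation, conjunction analysis and ROI extraction, and
    three-regression mediation analysis with Sobel tests and bootstrap
    confidence intervals. Includes a synthetic-data generator that emulates
    smoothed, modulated gray-matter volume maps with a known
    atrophy-mediated effect structure, so every stage is testable against
    ground truth, plus a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
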