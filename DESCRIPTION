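Package: socialpose3d
Title: Compact 3D Social Pose Features and Ridge Encoding Models for
    Social Scene Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether compact three-dimensional social
    pose features (per-agent face position and facing direction) explain
    human ratings of two-person social scenes as well as dense 3D body
    joints, and better than their 2D projections.  Provides a seeded
    synthetic-scene generator (two-agent 45-joint tracks, simulated rater
    panels, model embeddings with controlled pose information), pose
    feature construction with depth fusion and completeness filtering, a
    ridge-regression encoding framework with cross-validated
    regularization and layer selection, Johnson-Lindenstrauss-sized
    sparse random projection, grouped (banded) ridge with Dirichlet
    random search over group weights, semi-partial residualization, and
    seeded permutation tests for model-population comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
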