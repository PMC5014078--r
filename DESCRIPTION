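Package: lesionprog
Title: Lesion-Deficit Prognostic Models and Cross-Group Transfer for
    Post-Stroke Aphasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for lesion-deficit prognostic modelling of post-stroke
    language outcomes and for testing whether models learned in one patient
    group transfer to another.  Binary lesion masks in standard space are
    encoded as per-region lesion loads against a (possibly overlapping)
    parcellation; linear prognostic models are selected per task by iterated
    forward-selection/backwards-elimination driven by leave-one-out
    cross-validation error; systematic prediction-error shifts in a held-out
    group are tested with permutation-based family-wise error control and a
    random-feature-set model ensemble; and region-wise lesion-load/score
    correlations are screened with default (JZS g-prior) Bayes factors to
    distinguish shared from divergent lesion-deficit associations.  A
    synthetic-cohort generator produces toy atlases, territory-structured
    focal lesions and two-group cohorts with controllable sensitivity and
    intercept differences, so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    car,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
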