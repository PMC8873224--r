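Package: drscreen
Title: Feature-Based Diabetic Retinopathy Grading, Progression and
    Screening Evaluation
Version: 0.1.0
Authors@R:
    person("DR Screening Tools", "Maintainers", email = "maintainers@drscreen.example.org",
           role = c("aut", "cre"))
Description: Tools for feature-based diabetic retinopathy (DR) screening
    analysis. Maps sets of detected retinal lesions (microaneurysms,
    haemorrhages, exudates, cotton wool spots, venous abnormalities,
    IRMA, neovascularisation and more) to severity grades under two
    interchangeable grading schemes - the International Clinical
    Diabetic Retinopathy Severity Scale (ICDRS) and the UK National
    Screening Committee (NSC) scheme - via configurable decision
    tables, with a seeded bagged-tree ensemble grader as an alternative
    path. Provides disc/fovea-anchored retinal geometry (disc-diameter
    metric, five-region partition, quadrants), landmark-based
    similarity registration of baseline and follow-up images with
    lesion-level change detection (new, resolved, grown, shrunk),
    screening evaluation machinery (feature-conditioned confusion
    outcomes, sensitivity/specificity with Wilson or Clopper-Pearson
    confidence intervals, quadratic weighted kappa, ROC curves with
    dual operating points, prevalence subsampling), and a synthetic
    cohort generator that inverts the decision tables so every
    component is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
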