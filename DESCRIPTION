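Package: mriharvest
Title: De-Identification, Quality Assurance and Brain Volumetry for
    Clinical MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, filesystem-based pipeline for the secondary use
    of routinely acquired clinical brain MRI. Reads classic DICOM series,
    removes identifying header elements and facial features (defacing by a
    registered atlas mask), classifies MR sequences from acquisition
    parameters, checks brain field of view, segments brain tissue into
    cerebrospinal fluid, grey matter and white matter with an
    atlas-trained k-nearest-neighbour classifier, and extracts volumetric
    biomarkers (intracranial, brain, and per-tissue volumes). Includes a
    synthetic head-phantom and atlas generator with analytic ground truth
    for end-to-end validation, and the cohort statistics stage (report
    querying, age and interquartile-range filters, adjusted-mean linear
    models with Bonferroni post hoc tests, and step-wise success-rate
    accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
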