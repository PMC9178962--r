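Package: msageing
Title: Morphometric Similarity Networks and Normative Brain Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds morphometric similarity (MS) networks from regional
    cortical features, fits normative quadratic age trajectories of regional
    mean MS, classifies per-subject deviations as consistent or inconsistent
    with an accelerated-ageing profile, estimates brain-age gaps with a lasso
    age model, and relates regional MS to age and paired-associates-learning
    performance through permutation-tested partial least squares regression.
    Includes a synthetic-cohort generator with known ground-truth trajectories
    so that every stage of the pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
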