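Package: asymmeta
Title: Multi-Site Case-Control Analysis of Structural Brain Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A distributed-analysis toolkit for case-control studies of
    structural brain asymmetry across many imaging datasets. Computes
    left-right asymmetry indices from bilateral FreeSurfer-style regional
    measures (Desikan-Killiany cortical thickness and surface area,
    subcortical volumes), fits per-dataset covariate-adjusted linear models
    with eligibility and collinearity screening, converts diagnosis
    t-statistics to Cohen's d with standard errors and confidence
    intervals, pools effects by restricted maximum likelihood
    random-effects meta-analysis with Benjamini-Hochberg control within
    measure families, and runs moderator, outlier, interaction, medication
    and clinical-correlation analyses. A pooled individual-level arm
    applies empirical-Bayes batch harmonization, MANCOVA on all regional
    asymmetry indices (Wilks' lambda with Rao's F) and a stratified
    label-swapping permutation test. Includes a synthetic multi-site cohort
    generator with known ground-truth effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sva
Suggests:
    testthat (>= 3.0.0),
    metafor,
    car,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
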