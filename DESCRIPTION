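Package: serialbias
Title: Serial-Bias Analysis for Continuous Direction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serial dependence in continuous
    direction-report experiments with a concurrent Stroop load. Provides
    circular error arithmetic, removal of cardinal/oblique anisotropies from
    response errors by per-bin polynomial models with heteroscedastic noise,
    a density-asymmetry serial-bias statistic (scalar and as a rolling-kernel
    function of current-vs-previous dissimilarity), response-locked
    mouse-trajectory bias surfaces over a time-by-dissimilarity grid with
    cluster detection, first-frame bias-sign analyses, group-level contrasts
    with within-subject confidence intervals, a response-time-by-dissimilarity
    hierarchical slope estimate, and a synthetic-experiment generator that
    emulates the statistical structure of such studies for end-to-end
    validation and parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    knitr,
    lme4,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
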