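Package: pmwmorph
Title: Morphometry and Minimum-Work Optimality Analysis of Arterial Bifurcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for morphometric analysis of cerebral arterial bifurcations
    in case-control studies. Converts 3D bifurcation landmarks into observed
    branching angles and vessel radii, computes optimality indices derived from
    the principle of minimum work (junction exponent, predicted optimal
    branching angles, observed-minus-predicted deviations, asymmetry and area
    ratios), and runs the full case-control statistical layer: normality-gated
    group comparisons with post-hoc tests, tertile-coded univariate and
    stepwise multivariate logistic regression for aneurysm presence, and ROC
    analysis with Youden-index cut-offs. A seeded synthetic-cohort generator
    reproduces the three-group, five-site cohort structure so every pipeline
    stage can be exercised and validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
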