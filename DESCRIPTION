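Package: eduecon
Title: Economic Evaluation of Web-Based Versus Face-to-Face Health
    Professional Education
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Three-perspective economic evaluation of competing education
    delivery modes: provider break-even analysis with capacity-stepped
    fixed costs, health-service cost-effectiveness using the
    quality-adjusted students educated (QASE) metric and incremental
    cost-effectiveness ratios, and participant cost-benefit analysis with
    willingness-to-pay benefits. Includes a synthetic cohort generator
    emulating a randomized trial of face-to-face versus Web-based short
    courses, one-way sensitivity sweeps, and a configuration-driven
    reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
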