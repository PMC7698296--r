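Package: farmvisits
Title: Drivers of Vulture Visits to Livestock Farms from GPS Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying how GPS-tagged avian
    scavengers use livestock farms. Builds merged farm areas from buffered
    farm locations, classifies GPS fixes as farm visits using altitude-above-
    ground and speed criteria against a digital elevation model, computes
    kernel utilization-distribution home ranges and core areas, imputes
    carcass-abandonment probabilities with a logistic regression submodel,
    and fits binomial mixed models of farm use with crossed random
    intercepts, AICc-based multimodel inference, full model averaging, and
    spatial residual diagnostics. Includes a synthetic-data generator with
    known ground truth (true visit days, true model coefficients) so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
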