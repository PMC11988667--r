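Package: ocbatch
Title: Real-Time One-Class Authentication of Edible-Oil Batches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects adulterated samples inside an inspected batch of
    edible-oil composition profiles without any pre-built reference model.
    A Monte Carlo population of one-class partial least squares (OCPLS)
    models is fitted over random train/test splits of the batch, ranked by
    the sum of absolute centered residuals of each model's test set, and
    the theoretically expected number of all-authentic ("good") models is
    used to flag samples over-represented in those models' test sets.
    Includes a synthetic avocado-oil fatty-acid profile generator with
    ground-truth adulterant blends, and a rule-based chemical-marker
    screen for attributing the adulterant species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
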