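Package: woodlac
Title: Wood Lactation-Curve Analysis of Milk Fat Percentage from DHI
    Test-Day Records
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing daily milk fat percentage of dairy cattle
    from Dairy Herd Improvement (DHI) test-day records. Implements quality
    screening of test-day records, assignment of lactation months and
    non-genetic factor classes (farm size, parity, calving season, calving
    interval, 305-day milk yield), fitting of the minimum-shaped Wood
    incomplete-gamma lactation curve by damped Gauss-Newton least squares
    with an analytic Jacobian, closed-form derived traits (time to and value
    of the fat minimum, persistency), a five-factor fixed-effects
    least-squares-means analysis with Type-III partial F tests and Duncan's
    multiple range test, and a seeded synthetic-herd generator with exported
    ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    emmeans,
    MASS,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
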