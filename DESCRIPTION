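Package: actifda
Title: Functional Data Analysis of Collar-Mounted Accelerometer Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-minute activity counts from collar-mounted
    accelerometers worn by companion animals, built around the functional view
    of the 24-hour day. Provides preprocessing of minute-epoch counts
    (log(1+x) transform, 5-minute binning, baseline-day selection,
    weekday/weekend stratification, activity and intensity profiles),
    functional principal components analysis with modes of variation and
    cross-day-type score correlations, function-on-scalar regression with
    penalized-spline time-varying coefficients and subject-level bootstrap
    confidence bands, simulation-based likelihood-ratio tests for equality of
    mean curves, the projection-based two-sample Anderson-Darling test for
    equality of curve distributions, a synthetic cohort generator emulating
    feline circadian activity with and without degenerative joint disease, and
    an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
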