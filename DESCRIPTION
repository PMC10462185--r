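Package: homvol
Title: Homologous Hypothesis Tests for Tumor Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-sectional comparison of mean tumor volumes between two
    treatment groups at each time point of a longitudinal animal study,
    conditioning on the preceding time point to exploit the strong serial
    correlation typical of tumor growth curves. Provides the homologous
    hypothesis test (an interaction-regression contrast with n-4 degrees of
    freedom), the classical two-sample t-test comparator, a per-time-point
    study scanner producing report tables, a Monte-Carlo power and type-I
    error engine with a noncentral-t analytic oracle, and a synthetic
    log-linear AR(1) tumor-growth data generator. Includes a command-line
    interface for scanning studies, running power grids, and simulating data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
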