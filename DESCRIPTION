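Package: ifratest
Title: Nonparametric Tests of Exponentiality Against IFRA Alternatives via
    Cumulative Extropy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric goodness-of-fit tests of the exponential
    ("no-aging") hypothesis against alternatives in the increasing failure
    rate average (IFRA) class and its dual (DFRA), built from cumulative
    residual and cumulative past extropy of the first-order statistic. The
    test statistics are L-statistics with signed weight functions indexed
    by an order-statistic parameter n and a scaling parameter b, with
    scale-invariant versions, Jones-Zitikis variance estimators, asymptotic
    and Monte Carlo calibration, a Kaplan-Meier plug-in extension for
    right-censored data, classical competitor tests (Deshpande, Aly,
    Jammalamadaka), total-time-on-test diagnostics, a Monte Carlo power
    engine over standard lifetime families, and four classical reliability
    datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
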