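Package: hvcdm
Title: Key Points of Hydraulic Vulnerability Curves by the Differential
    Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits hydraulic vulnerability curves (loss of xylem hydraulic
    conductivity against water-potential tension) with the Weibull
    cumulative distribution function and locates their three key points --
    the air-entry point, the point of fastest conductivity loss, and the
    lethal point -- by the differential method, i.e. as roots of the fitted
    curve's second and third derivatives, alongside the traditional
    quantile readings at 12, 50 and 88 percent loss.  Includes raw
    air-injection and conductivity computations, xylem water-balance
    estimation, one-sample and bracketing validation tests, seeded
    synthetic-data generators, and a CSV/JSON analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
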