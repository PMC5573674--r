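Package: mutscale
Title: Mutation-Rate and Growth-Rate Scaling Under Bacterial Genome Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of coordinated mutation-rate and
    growth-rate changes along an engineered genome-reduction series in Escherichia
    coli. Implements Luria-Delbruck fluctuation-assay inference (MSS/Lea-Coulson
    maximum likelihood, P0 estimator, CFU plate-count processing), exponential
    growth-rate estimation from OD600 time series, log-log scaling-law fits of
    mutation rate against genome size and against growth rate, permutation-based
    correlation statistics and a paired media-shift test, deleted-gene category
    correlation analysis, a daily serial-transfer evolution simulator with
    generation accounting, and a synthetic-data generator that emulates every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
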