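Package: coopnet
Title: Physician Cooperation Networks from Outpatient Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds yearly patient-sharing networks of physician practices
    from outpatient claims data, computes network- and node-level indicators
    of professional cooperation (density, mean distance, a random-graph
    normalized mean-distance statistic, and degree, eigenvector and
    betweenness centrality rankings), assembles unbalanced practice-year
    panels, and estimates dynamic panel models of cooperation by two-step
    Blundell-Bond system GMM with Windmeijer-corrected standard errors and
    the Sargan, Arellano-Bond autocorrelation and Wald diagnostic battery.
    Includes a seeded synthetic claims generator emulating a regional
    integrated-care setting for method evaluation, plus sensitivity analysis
    over the shared-patient edge threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
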