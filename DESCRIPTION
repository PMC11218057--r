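Package: aggdoe
Title: Design-of-Experiments Optimization of Stem-Cell Suspension Culture Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing induced pluripotent stem cell (iPSC)
    suspension-culture media by factorial design of experiments. Generates
    D-optimal interaction designs with center points and batch assignment,
    estimates exponential growth kinetics from daily bioreactor counts,
    quantifies aggregate stability through a volume-based prediction error
    that separates proliferation from fusion, fits multiple linear regression
    interaction models with the standard DoE quality metrics (R2, Q2,
    lack-of-fit model validity, replicate reproducibility), and locates
    multi-response optima by desirability functions with process-capability
    (Cpk) and probability-of-failure summaries. A synthetic bioreactor
    campaign generator with known ground truth (run-dependent growth rates,
    stochastic aggregate fusion and fragmentation, marker and qPCR responses
    from a known coefficient structure) supports end-to-end testing of every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
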