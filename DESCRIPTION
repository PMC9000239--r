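Package: flexmcr
Title: Flexible Trilinearity-Constrained Multivariate Curve Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate curve resolution by alternating least squares
    (MCR-ALS) for three-way chromatographic and spectroscopic data, with a
    per-component trilinearity constraint that can be switched between
    bilinear, trilinear, and trilinear-with-peak-shift-correction modelling.
    Includes augmented-matrix rank diagnostics for choosing a model,
    purest-variable (SIMPLISMA-style) initial estimates, non-negative least
    squares, PARAFAC and ATLD reference solvers, profile-recovery metrics,
    seeded synthetic data generators emulating LC-DAD, GC-MS and
    flow-injection-analysis experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
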