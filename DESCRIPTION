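Package: crankfit
Title: Limited-Volume Fickian Release Kinetics for Active Packaging Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and fits the release kinetics of an antioxidant from a
    plane-sheet active packaging film into a finite, well-stirred food
    simulant. Implements the limited-volume Fickian series solution with its
    transcendental eigenvalue problem tan(q) = -alpha*q, the short-time
    complementary-error-function model used when the volume ratio alpha is
    small, deterministic diffusion-coefficient estimation with goodness of
    fit, an independent finite-difference solver of Fick's second law used
    as a numerical oracle, a synthetic release-curve generator emulating a
    two-simulant, two-temperature release study, and small utilities for
    swelling-ratio and antioxidant summary arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
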