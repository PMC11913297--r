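Package: cicapprox
Title: Cross-Entropy Information Criterion for Approximating Unnormalized Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric approximation of a density known only through an
    expensive unnormalized evaluator r(x), with joint estimation of the
    normalizing constant. Implements adaptive importance sampling with
    Gaussian-mixture proposals fitted by importance-weighted EM (the minimum
    cross-entropy estimator), and selects the number of mixture components by
    minimizing the cross-entropy information criterion, an AIC-style penalty
    scaled by the estimated normalizing constant. Includes synthetic targets
    with closed-form normalizing constants (in-family mixtures, half-space
    rare-event indicators, conjugate normal posteriors) and quadrature and
    Monte-Carlo oracles for validation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
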