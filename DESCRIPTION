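Package: lmsnorms
Title: Age-Conditional Test Norms via the Weighted LMS Method
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs age-conditional reference norms (z-scores, centiles,
    and centile charts) for bounded, skewed test scores using the LMS method:
    smooth age-varying Box-Cox power L(t), median M(t), and generalised
    coefficient of variation S(t) curves estimated by penalized maximum
    likelihood with cubic-spline smoothing under sampling weights.  Includes
    sequential equivalent-degrees-of-freedom model selection by deviance
    criteria (SBC, AIC, GAIC(3)), two-step inverse-probability weight
    construction for two-phase stratified designs, a synthetic two-phase
    cohort generator with known ground truth, a Q-test goodness-of-fit
    diagnostic, and a serialisable raw-score-to-standard-score calculator.
License: MIT + file LICENSE
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
    optparse
Config/testthat/edition: 3
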