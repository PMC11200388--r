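Package: stepbench
Title: Benchtop Pre-Validation of Wearable Pedometer Settings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Software stand-in for a mechanical continuous stepper used to
    pre-validate embedded pedometer settings before human trials. Simulates
    optical ground-truth traces and foot-impact impulse trains over a range
    of walking cadences, reproduces the threshold/debounce step-detection
    state machine of a commercial inertial sensor, derives converged
    ground-truth step counts through a quantize/smooth/alternation pipeline,
    fits a multivariate polynomial regression of signed step-count error on
    normalized settings and cadence with cross-validated order selection,
    and recommends setting combinations per cadence range via a weighted
    composite of mean absolute error and error standard deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
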