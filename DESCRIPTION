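Package: v1adapt
Title: Orientation Adaptation in Primary Visual Cortex via a Mixture of
    Gaussian Scale Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates orientation adaptation phenomenology of V1 neurons
    (suppression, repulsion, orthogonal facilitation, response maintenance,
    and attractive tuning shifts) with a mixture of Gaussian scale mixtures
    (MGSM) model of classical and extra-classical receptive field
    interactions.  Provides an oriented quadrature filter bank, closed-form
    Gaussian scale mixture inference with quadrature cross-checks,
    expectation-maximisation training on image patches, mixed-dataset
    adaptation of the model state, a prior-based winner-take-all readout,
    declarative covariance perturbations, and orientation tuning curve
    measurement with adaptation metrics.  Synthetic grating and
    natural-surrogate texture generators make the whole pipeline
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    ggplot2,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
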