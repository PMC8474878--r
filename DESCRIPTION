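Package: seizecast
Title: Bayesian Convolutional Networks for Probabilistic Seizure Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for probabilistic epileptic-seizure forecasting from
    multichannel scalp EEG. Implements a convolutional neural network with
    Gaussian mean-field variational weight posteriors trained by stochastic
    ELBO minimisation, a Bayesian modulator that fuses auxiliary evidence
    (e.g. circadian seizure timing estimated by Gaussian kernel density
    estimation) into the network's pre-softmax output, Monte-Carlo
    predictive sampling with an explicit uncertainty level, evaluation
    under the seizure-prediction-horizon / seizure-occurrence-period alarm
    paradigm, and an attention-map probe of the first convolutional layer
    for biomarker exploration. A synthetic EEG generator with controllable
    preictal slow-wave signatures makes the full pipeline testable without
    access to restricted clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
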