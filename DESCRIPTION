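Package: nirsbci
Title: Simulation, Preprocessing, and Classification for fNIRS
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("nirsbci", "developers", email = "nirsbci@example.org",
           role = c("aut", "cre"))
Description: Tools for three-class (rest, right-, left-hand motor execution)
    classification of functional near-infrared spectroscopy (fNIRS)
    recordings.  Includes conversion of optical-density changes to
    oxy-/deoxy-hemoglobin concentration changes via the modified
    Beer-Lambert law, wavelet multiresolution denoising with
    band-limited (d8+d9) reconstruction, time-domain statistical feature
    extraction, linear support vector machines on principal components,
    fully connected neural networks, one-dimensional convolutional
    neural networks over multichannel time series, stratified k-fold
    cross-validation with hyperparameter grid search, sample-size
    learning curves, convolutional-filter channel attribution, and a
    seeded synthetic-session generator emulating block-design motor
    tasks with physiological noise.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
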