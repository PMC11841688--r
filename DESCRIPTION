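Package: avmotion
Title: Audio-Visual Motion Integration During Active Self-Movement
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of audio-visual cue integration for
    actively moving observers. Generates gain-coded left/right motion
    judgments under self-generated yaw head rotation from a generative
    observer whose compensated auditory and visual cues share a single
    self-movement noise source; fits cumulative-Gaussian psychometric
    functions with a constrained lapse rate; fits an across-trial-noise
    psychometric model that marginalizes over head-velocity variability;
    predicts audio-visual bias and precision from unimodal conditions under
    body-centered integration (BCI), body-centered integration adjusted for
    shared self-movement noise (BCI+), and image-centered integration (ICI);
    and evaluates model predictions via squared-error tables, bootstrap
    confidence intervals of prediction-minus-empirical differences, and
    RMSE of model-implied psychometric curves. Includes head and eye
    kinematics preprocessing: zero-phase lowpass filtering, turn detection,
    sweep median velocity, jerk-based saccade rejection, and the expected
    vestibulo-ocular reflex velocity.
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
    withr
Config/testthat/edition: 3
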