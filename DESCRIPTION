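Package: perturbreach
Title: Simulation and Analysis of Motor Cortical Activity Under Target
    Orientation Perturbations
Version: 0.1.0
Authors@R:
    person("perturbreach", "developers", email = "dev@perturbreach.invalid",
           role = c("aut", "cre"))
Description: Tools for studying single-unit primary motor cortex activity
    recorded while a subject reaches to grasp a target whose orientation can
    be abruptly rotated shortly after movement onset.  Provides a synthetic
    session generator with known ground truth (block design, minimum-jerk
    hand-orientation trajectories, inhomogeneous-Poisson spike trains),
    trial-epoch firing-rate statistics with task-related / corrective /
    anticipatory unit classification, perturbation reaction-time estimation
    from orientation trajectories via confidence-band deviation detection,
    perievent rasters and histograms, and a two-layer backpropagation
    network decoder of perturbation conditions from single-unit activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
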