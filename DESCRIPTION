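Package: antnav
Title: Kinematics, Path Straightness and Odour-Avoidance Analysis for
    Ascending Ant Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the vertically ascending foraging
    trajectories of ants digitised as frame-by-frame head and thorax
    coordinates.  Computes per-frame kinematics (step lengths, turning
    angles, stop-excluded speed, body-axis orientation and its angular
    velocity), path-straightness indices (sinuosity and maximum expected
    displacement), detects stationary scanning bouts, classifies each
    trip's interaction with an odour band (walked over, detour, U-turn),
    and runs the associated inference layer (Welch t-tests per nest,
    one-way repeated-measures ANOVA with a priori Helmert contrasts).
    Includes a correlated-random-walk forager simulator with implanted
    behavioural events and known ground truth, so every analysis stage
    can be validated without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
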