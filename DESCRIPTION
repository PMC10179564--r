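Package: kinfresh
Title: Feature Relevance Selection for Upper-Limb Motion-Capture Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse three-dimensional upper-limb marker
    trajectories from reach-and-lift tasks. From raw marker positions the
    package unifies movement side by sagittal-plane reflection, crops each
    recording to the lift-lower phase using a vertical-excursion threshold,
    derives per-marker kinematic time series (trajectory, displacement,
    velocity, acceleration and their Euclidean modules), min-max normalises
    them, maps every series to a catalogue of scalar features, and selects
    class-relevant features by per-feature hypothesis tests (Mann-Whitney U
    for real-valued features, two-sided Fisher exact for binary features)
    with Benjamini-Yekutieli false-discovery-rate control under a
    one-vs-rest decomposition of three limb classes. Significant features
    common to all binary problems are aggregated by marker, movement axis
    and signal domain. A minimal-jerk cohort simulator with configurable
    class effects makes every stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    e1071,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
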