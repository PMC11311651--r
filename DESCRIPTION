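Package: bladderchip
Title: Invasion Quantification for a Bladder-Cancer-on-a-Chip Model
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies bladder cancer cell invasion in a five-channel
    microfluidic chip whose channels are separated by rows of 16 posts.
    Implements the two standard readouts of the assay: the number of
    inter-post thresholds (IPTs) crossed out of 17, and the maximum
    distance of invasion into the upper Matrigel channel, both computed
    from segmented fluorescence or brightfield microscopy images in
    calibrated micrometre coordinates. Includes a parametric chip-geometry
    model, a minimal grayscale TIFF reader/writer, Otsu-threshold cell
    segmentation with connected-component labeling, labeling-positivity
    estimation, one-way ANOVA with Tukey HSD post hoc comparisons,
    dose-response summaries, and an agent-based biased-random-walk
    simulator that generates ground-truthed synthetic chip experiments,
    including dose-dependent migrastatic inhibition arms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
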