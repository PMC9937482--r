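Package: panogaze
Title: Eye and Head Scanpath Analysis for 360-Degree Panoramic Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye and head movements recorded while observers
    explore 360-degree panoramic scenes, for example in a virtual-reality viewer.
    Provides spherical geometry primitives (great-circle metric, spherical means,
    quaternion slerp), reconstruction of world-frame gaze from eye-in-head vectors
    and head-pose quaternions, dispersion-threshold (I-DT) fixation detection
    adapted to spherical stimuli, equirectangular heatmaps with latitude-weighted
    correlations, cross-recurrence quantification of scanpath similarity between
    encoding and recognition, and a synthetic-study generator with controllable
    image-driven versus participant-idiosyncratic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
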