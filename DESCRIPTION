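Package: fid3b
Title: Bayesian Blinking and Bleaching Localization Microscopy with an
    Intensity-Distribution Birth Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of super-resolution images from high-density
    blinking/bleaching fluorescence image sequences in the style of the
    Bayesian analysis of bleaching and blinking (3B) approach, extended
    with a fluorescence-intensity-distribution birth prior (FID3B).
    Includes a three-state (emitting / not emitting / bleached)
    hidden-Markov simulator of dense emitter data with pixel-integrated
    Gaussian optics and Poisson-plus-Gaussian camera noise, the
    transition-probability-weighted intensity prior for proposing new
    fluorophores, a marginal-likelihood model-selection engine with
    birth/death moves, probability-map rendering, and evaluation tools
    (global structural similarity, distance-to-structure statistics,
    retained/discarded position accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
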