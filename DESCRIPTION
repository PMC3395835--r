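Package: fallsense
Title: Fall Detection from Tri-Axial Accelerometry with Wavelet Features,
    Swarm Clustering and a Neural Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Detects falls in waist-worn tri-axial accelerometer streams.
    Impact-triggered 5-second windows are normalized, reduced to 13
    dimensions by a third-order Haar discrete wavelet transform, and
    classified by an ensemble of a multilayer perceptron and an augmented
    radial basis function network, both trained with resilient
    backpropagation. Cluster structure learned by regrouping particle swarm
    optimization seeds both the radial basis layer and a Gaussian
    cluster-knowledge augmentation scheme that multiplexes each query into
    a majority vote. Includes a synthetic signal generator emulating fall
    and activities-of-daily-living morphologies, per-stratum
    sensitivity/specificity evaluation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
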