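Package: hemoscape
Title: Systems-Level Analysis of Multivariable Hemodynamic Image Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the hemodynamic landscape of angiogenic
    microenvironments from co-registered wide-field optical image time-series of
    microvascular oxygen saturation, blood volume and blood flow. Provides the
    pre-processing chain (temporal running-mean filtering, block-wise spatial
    aggregation, fractional-change series), five analysis modules (hypoxic
    wavefront propagation tracking, seed-based correlation clustering of
    vasomotion niches with SVD initialization, blood-flow/blood-volume coupling
    classification, stimulus-response mapping under a gas-inhalation paradigm,
    and band-wise spectral power mapping), and a synthetic-scene generator that
    plants known wavefronts, niches, coupling structure, boxcar responses and
    sinusoidal spectral content for validation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
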