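Package: poptensor
Title: Space-by-Time Tensor and Matrix Factorizations of Population Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes single-trial population spike trains into
    trial-invariant spatial, temporal and spatiotemporal firing modules with
    trial-dependent activation coefficients. Implements non-negative Tucker-2
    ("space-by-time NMF") and orthogonal Tucker-2 tensor factorizations,
    spatiotemporal and space-only matrix factorizations (NMF, PCA, ICA, FA),
    geodesic module similarity with optimal matching, stimulus decoding from
    activation coefficients via regularized multiclass linear discriminant
    analysis with leave-one-out module-count selection, rank-order latency
    decoding, and permutation procedures that isolate the spatial, temporal,
    latency and temporal-precision contributions to a population code. Ships
    an inhomogeneous-Poisson spike-train simulator with configurable block
    firing patterns for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    generics,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
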