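Package: gnmhotspots
Title: Hot-Spot Residue Identification from Gaussian Network Model Fast Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-protein interaction hot-spot residues from the
    intrinsic dynamics of unbound structures. Builds the Gaussian network model
    (GNM) Kirchhoff matrix from a C-alpha trace, extracts its high-frequency
    normal modes, encodes per-residue feature vectors from single or combined
    fast modes with a sliding window, and classifies residues with a
    Gaussian Naive Bayes model under chain-level cross-validation. Includes
    mean-square-fluctuation threshold baselines, mean-square-distance-fluctuation
    scoring, a grid search over cutoff, window and mode settings, and a
    synthetic C-alpha chain generator with planted labels so the full pipeline
    is testable without structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
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
    testthat (>= 3.0.0),
    e1071,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
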