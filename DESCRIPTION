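Package: sacphys
Title: Synaptic Connectivity and Direction Selectivity Analysis for
    Retinal Starburst Amacrine Cell Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing paired whole-cell voltage-clamp recordings
    from retinal starburst amacrine cells and spike recordings from
    direction-selective ganglion cells. Implements a semi-automated
    classifier for synaptic connections (peak, trial-presence and
    latency/rise-time criteria), autapse detection by double-exponential
    fitting of depolarisation-evoked transients and residual thresholding,
    Boltzmann-fit onset latencies, vector-sum direction-selectivity
    indices, distance-binned connection probabilities with binomial
    errors, a Monte-Carlo null for reciprocal connectivity, density
    recovery profiles of cell mosaics, and a circle-intersection model of
    dendritic overlap. A seeded synthetic-data module generates current
    traces with planted postsynaptic events, direction-tuned Poisson
    spike trains, exclusion-zone mosaics and connectivity tables with
    ground truth recorded in metadata, so every estimator can be tested
    against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
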