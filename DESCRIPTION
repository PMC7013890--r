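Package: qdetect
Title: Geographical Detectors for Spatial Stratified Heterogeneity in
    Accident Severity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variance-decomposition ("q statistic") analysis of spatial
    stratified heterogeneity in point-event severity data, with the four
    classical geographical detectors: the factor detector (q with
    permutation or noncentral-F significance), the influence/risk detector
    (pairwise Welch comparisons of stratum means), the ecological detector
    (F ratio of within-strata variance sums) and the interaction detector
    (q of the overlay of two stratifications, classified into weaken /
    enhance / independent / nonlinear-enhance types).  Includes a global
    Moran's I spatial-dependence check on k-nearest-neighbour weights, a
    synthetic accident-record generator with planted heterogeneity,
    planted interactions and spatial clustering (including a preset
    calibrated to the published Shenzhen 2014-2016 summary statistics),
    and a reporting pipeline producing factor tables with significance
    masking, sub-strata risk comparisons, all-pairs interaction matrices
    and top-k combined-factor rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
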