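Package: arcoephys
Title: Electrophysiology and Morphometry of Songbird Arcopallial Upper Motor Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the cellular specializations that let
    zebra finch vocal-motor neurons (RAPNs, projection neurons of the robust
    nucleus of the arcopallium) fire ultranarrow action potentials compared
    with neighbouring non-vocal motor neurons (AId). Provides a single
    compartment conductance-based neuron simulator with a high-threshold
    fast-gating Kv3 conductance and pharmacological modulation (TEA, 4-AP,
    AUT5), action-potential waveform feature extraction (half-width,
    phase-plane depolarization/repolarization rates, threshold, AHP), passive
    membrane property estimation (tau_m, R_in, C_m and capacitance-derived
    surface area), voltage-clamp current decomposition by drug subtraction,
    SWC-based neuronal morphometry (Sholl profiles, spine densities, frustum
    surface areas, voxelized volumes, soma contour triangulation), in situ
    hybridization densitometry and labeled-cell counting, and the group
    comparison statistics used throughout, together with synthetic-data
    generators so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    EBImage,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
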