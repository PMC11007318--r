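Package: adaptmap
Title: Simulation and Analysis of fMRI Repetition-Suppression Mapping of Spatial Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carry-over fMRI adaptation studies of spatial navigation
    on a linear track: second-order counterbalanced (de Bruijn) event sequences
    and trial timing, a synthetic BOLD generator whose voxels implement
    tuning-curve-based repetition suppression, first-level GLMs with parametric
    adaptation modulators (inter-location distance, location identity, path
    length, response, temporal distance), group-level statistics with
    winsorization, directional JZS Bayes factors and sign-flip maximum-statistic
    permutation correction, cross-validated adaptation-pattern distinction
    scores, one-dimensional neural-space reconstruction by classical MDS with a
    Procrustes permutation test, and a simplified connectopic-gradient
    segmentation of a region of interest into ordered portions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    RNifti
Config/testthat/edition: 3
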