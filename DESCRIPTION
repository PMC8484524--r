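Package: tripledfc
Title: Sliding-Window Dynamic Functional Connectivity Variability in the
    Triple-Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based dynamic functional connectivity (DFC) variability
    analysis of resting-state fMRI for three-group cohort studies (healthy
    controls, subjective cognitive decline, amnestic mild cognitive
    impairment). Implements minimal volumetric preprocessing (volume discard,
    motion exclusion, Friston-24 plus tissue-signal nuisance regression,
    band-pass filtering, detrending, Gaussian smoothing), spherical-seed
    network template definition via one-sample permutation inference with
    threshold-free cluster enhancement (TFCE), sliding-window Fisher-z
    connectivity variability maps, voxelwise ANCOVA and post-hoc group
    contrasts with Freedman-Lane permutation and cluster-extent or TFCE
    family-wise error control, covariate-adjusted brain-behavior correlation,
    and logistic-regression diagnostic models with backward elimination and
    ROC summaries. Ships a synthetic-cohort generator with known ground-truth
    time-varying coupling so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
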