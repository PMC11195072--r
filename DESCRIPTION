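Package: mtsrep
Title: Interpretable Feature-Space Representations for Case-Control
    Classification of Multivariate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents labeled multivariate time-series datasets (such as
    region-by-time resting-state fMRI recordings) in five interpretable
    feature spaces: per-unit dynamical features, per-feature brain-wide
    maps, their combination, pairwise-coupling matrices, and the union of
    local and pairwise properties. Provides a bank of 25 univariate
    time-series features and 14 statistics of pairwise interactions
    (including transfer entropy, phase slope index and dynamic time
    warping), a repeated stratified cross-validation harness with
    outlier-robust sigmoidal normalization, inverse probability weighting
    and balanced accuracy, permutation nulls with a Gaussian tail
    approximation and Benjamini-Hochberg correction, corrected resampled
    t-tests for paired model comparison, fold-wise best-model selection,
    and a vector-autoregressive synthetic data generator with plantable
    case-control effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
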