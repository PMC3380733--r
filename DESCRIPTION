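Package: ms2quality
Title: Unsupervised Quality Assessment of Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the quality of tandem mass (MS/MS) spectra without any
    training data, so that poor-quality spectra can be filtered out before
    database search. Ten spectral quality features (complementary-ion pair
    intensity, uncharged precursor mass, amino-acid mass-difference counts,
    delta-mass statistics, Good-Diff fraction, neutral-loss and supportive-ion
    pair counts, intense-peak ratio) are computed per spectrum, binarized by a
    percentile rule into per-feature high/poor calls, and integrated through a
    constrained bipartite-graph consensus optimization solved by an alternating
    quadratic algorithm with guaranteed row-stochastic iterates and
    non-increasing cost. Includes MGF peak-list input/output, ROC evaluation
    against external labels, and a synthetic spectrum generator with known
    labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
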