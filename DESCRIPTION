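Package: restfc
Title: Static and Dynamic Resting-State Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four complementary analyses of resting-state BOLD time series
    parcellated into regions of interest: static Pearson functional
    connectivity with robust (scaled-MAD) outlier screening, sliding-window
    connectivity variability with a window-length assessment, point-process
    reduction of the signal to suprathreshold events with pairwise
    co-activation counting, and graph-theoretic network measures
    (characteristic path length, clustering coefficient, mean degree) on
    binarized connectivity matrices. Edge-wise and scalar one-way ANOVA with
    Bonferroni-corrected pooled-variance post-hoc comparisons screen for
    group differences across a multi-group cohort. A band-limited Gaussian
    surrogate generator produces covariance-structured multi-subject BOLD
    cohorts with planted edge-level group differences, together with exact
    and Rice-type analytic predictions of threshold-crossing rates, so the
    whole pipeline can be exercised and calibrated without access-restricted
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
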