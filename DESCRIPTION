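Package: repliseg
Title: Segmentation and Classification of DNA Replication Timing Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits continuous piecewise-linear models to genome-wide time-of-
    replication (ToR) profiles measured as normalized S/G1 ratios on tiling
    arrays. Candidate constant and fork-rate-bounded sloped lines are detected
    per window with a Hough transform, assembled into a continuous
    whole-chromosome segmentation by dynamic programming, and refined by
    constrained least squares. Every locus is classified as constant timing
    region (CTR), temporal transition region (TTR) or undefined near segment
    boundaries. Includes a synthetic-profile simulator with known ground
    truth, a benchmark harness (RMSE and classification accuracy as a
    function of distance from segment ends), inter-sample map comparison,
    ToR-matched CTR/TTR probe pairing, windowed feature densities, and
    CTR-residence enrichment against matched random control regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
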