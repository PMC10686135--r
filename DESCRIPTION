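Package: trackforest
Title: Pedigree-Forest Statistics for Video-Based Single-Cell Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to refine ("compress") data from video-based single-cell
    tracking: read and validate per-frame position tables and lineage tables,
    assemble pedigree forests, classify lineages by death and survival,
    parametrize population growth curves with a fixed-intercept cubic
    polynomial, kernel-smooth trajectories to derive speed and moving
    generalized power means, compute sister-cell joint statistics (descendant
    counts, subtree track lengths, kernel density estimates), mean squared
    displacement and sibling cross-displacement curves with a
    persistent-random-walk memory-time fit, and detect prolonged cell-cell
    proximity events. A branching-process trajectory simulator with heritable
    lineage traits generates synthetic datasets with the statistical structure
    these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
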