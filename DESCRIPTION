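Package: listcomp
Title: Threshold-Free Comparison of Ranked Gene Lists
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric, threshold-free testing of whether two ranked
    differential-expression gene lists share a statistically significant
    common gene set, with estimation of the size and membership of that set.
    Implements a stepwise "marching" overlap algorithm based on exact
    hypergeometric tail probabilities, an increment test for the growth of
    the overlap between consecutive steps, shuffle-based simulation for
    validation, overlap-distance hierarchical clustering of many experiments,
    cross-species signature construction via homolog mapping, and
    microarray-style fold-change preprocessing (percentile filtering and
    probeset collapsing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
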