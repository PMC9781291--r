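Package: capnet
Title: Dynamic Directed Graphs of Calcium Signal Propagation in Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects calcium events in per-cell fluorescence traces using
    forward and backward exponential-moving-average crossings with a
    piecewise-linear baseline through local minima, builds a frame-resolved
    directed graph of cell-to-cell signal propagation from staggered event
    overlap between spatially adjacent cells, compresses it into a weighted
    directed transmission graph, and computes network metrics (active-cell
    share, per-frame transmission maxima, degree and HITS hub/authority
    centralities) and per-100-cells group histograms with rank-sum group
    comparisons. Includes a synthetic-culture simulator with known ground
    truth for end-to-end validation, readers and writers for trace and event
    tables, TIFF stacks and label images, GraphML exports, and ggplot2
    visualisations of traces, graphs and histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
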