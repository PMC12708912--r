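Package: hotspotr
Title: Grid-Based Diversity Hotspot Identification and Conservation Gap
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for conservation prioritization from species occurrence
    records on a regular planar grid: species richness, greedy
    complementarity (set-cover) selection and weighted endemism (range-size
    rarity) surfaces per species subset; multi-threshold hotspot
    identification with consensus classes and rank-sum priority ordering;
    overlay of two-tier nature-reserve layers to quantify conservation
    effectiveness and gaps at the cell, species and occurrence-record
    levels; and post-processing of habitat-suitability surfaces under
    current and future climate scenarios into richness-change maps,
    habitat contraction/expansion classes and loss-of-suitable-area threat
    reclassification. Includes a fully parameterized synthetic-data
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
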