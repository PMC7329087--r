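Package: fsopa
Title: Criterion-Ranked Compression Phylograms for Feature Sensitivity in
    Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature-sensitivity analysis for mixed-type tabular data with a
    survival-style outcome. Samples are ranked by a criterion (for example
    hospital length of stay) and split into best/worst subsets at three
    selection-pressure levels; each subset is summarised as a phylogram of
    the dataset's features built from normalized compression distances with
    neighbor joining and annotated with fast greedy modularity communities.
    Principal features are extracted by comparing tree structure between
    best and worst models (clade-based and target-based procedures), refined
    across column-constrained resamplings, and evaluated with Cox
    proportional-hazards models under forward-AIC selection and
    non-dominated (Pareto) multicriteria comparison. Includes a synthetic
    generator of EHR-like tables with Cox-structured outcomes and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
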