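Package: bpofs
Title: Binary Political Optimizer for Wrapper Gene Selection
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Wrapper feature selection for gene-expression matrices using a
    binary Political Optimizer, a population metaheuristic whose phases mimic
    party formation, election campaigning with recent past-based position
    updating, party switching, elections and parliamentary affairs. Continuous
    member positions are mapped to binary gene masks through S-shaped
    (sigmoid) or V-shaped (|tanh|) transfer functions, and candidate subsets
    are scored by k-nearest-neighbour accuracy under stratified
    cross-validation combined with a sparsity reward. Includes a synthetic
    expression-data generator with planted informative genes, an exhaustive
    subset-search oracle for small feature spaces, an experiment harness with
    summary statistics and Wilcoxon signed-rank comparisons, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    caret,
    class,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
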