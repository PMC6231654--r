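Package: omicsvote
Title: Vote-Counting Meta-Analysis and Network Integration of Multi-Omics
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonises per-study differential-expression tables across
    microRNA, protein and metabolite layers and combines them by vote
    counting: Fisher's method for within-study p-value combination,
    layer-specific fold-change cutoffs, regulation-direction frequency
    stratification and a majority consensus-direction rule. Downstream
    stages score pathways by hypergeometric over-representation with a
    degree-centrality topology score, reduce the cross-study log2
    fold-change matrix by PCA and non-metric multidimensional scaling,
    and assemble an expression-annotated heterogeneous molecular
    interaction network. A seeded synthetic-corpus generator provides
    ground-truth benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
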