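Package: morphodyn
Title: Dynamic Network Analysis of Early Hebrew Verb Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-recording bipartite networks of Semitic verb roots
    and inflected binyan patterns from coded dyadic (child and child-directed)
    speech, computes node degree, eigenvector centrality and network density
    over developmental time, and fits lagged mixed-effects adaptation models
    of child-parent coupling. Includes a calibrated synthetic dyad simulator
    with known ground-truth couplings for parameter-recovery validation, a
    full morphological inventory of the seven binyan conjugations with their
    temporal patterns and agreement inflections, and tidy accessors and
    plotting helpers for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
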