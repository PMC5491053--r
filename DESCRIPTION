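Package: hospmap
Title: Semi-Supervised Diffusion Maps of Hospital Quality-Measure Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organizes entities (hospitals) by their standardized performance
    profiles across many quality measures. Implements coupled diffusion
    co-organization of measures and entities (cosine-affinity diffusion metric
    on measures, tree-approximate earth mover's distance on entities), binary
    partition trees on low-frequency diffusion eigenvectors, expert-scored
    reference profiles with kernel-regression score propagation, an ensemble
    of small feedforward networks whose hidden-layer features define a heat
    kernel and a 3-D diffusion map, and k-center heat-source neighborhoods
    with domain-level profile characterization. A synthetic-data generator
    with planted cluster and domain structure makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    pracma,
    withr
Config/testthat/edition: 3
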