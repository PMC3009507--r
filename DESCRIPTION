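Package: funcoh
Title: Functional Coherence of Biomolecule Sets and Network Proximity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-content based semantic similarity for ontology terms and
    annotated biomolecules, coherence measures for whole modules (average pairwise,
    generalized, graph and weighted information content), size adjustment against
    random backgrounds and a binormal index of detectability, together with random
    walk with restart proximity for interaction networks and the binned
    correlation analysis connecting functional similarity to topological
    proximity. Includes readers for OBO ontologies, GAF and pfam2go-style
    annotation files, edge lists and module lists, plus deterministic synthetic
    generators for ontologies, annotation corpora, module collections and
    planted-partition networks.
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
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
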