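Package: longnet
Title: Longevity-Network Construction and RNAi Lifespan Screen Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds longevity networks from protein-protein interaction edge
    lists by retaining a core set of longevity-associated genes, adding their
    first-order interaction partners and extracting the largest connected
    subgraph. Provides permutation tests for gene-set interconnectivity
    against randomized gene sets, cross-species candidate transfer through
    many-to-many orthology maps, essentiality-based candidate filtering, and
    the downstream statistics of a post-developmental RNAi lifespan screen:
    thrashing-assay phenotype calling, Kaplan-Meier and log-rank survival
    comparison, lifespan effect measures, verification-frequency and
    extrapolation summaries. A synthetic-data module generates scale-free
    interactomes with planted high-interconnectivity modules, orthology maps,
    essentiality labels, Gompertz lifespan samples and binomial thrashing
    fractions so the full pipeline can be exercised with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    flexsurv,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
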