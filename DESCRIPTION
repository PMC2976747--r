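Package: coexdiff
Title: Differential Topology of Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds region-specific gene co-expression networks over a shared
    gene set using rank-and-threshold Pearson correlation edge rules, computes
    a per-gene cross-network topological overlap statistic, extracts genes
    with zero topological overlap between the two networks, and assesses their
    count against a degree-preserving rewiring null model. Includes a
    SAM-style permutation test for differential expression, a hypergeometric
    gene-set enrichment test against GMT collections, a fully seeded synthetic
    two-region data generator with planted ground truth, and an end-to-end
    pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
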