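Package: prophagenet
Title: Gene-Sharing Networks, Clustering and Host-Range Analysis for
    Prophage Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cataloging predicted prophages from bacterial
    genome collections. Builds homologous gene families by pairwise
    alignment scoring, a minbit similarity filter and Markov clustering
    (MCL); derives genome- and gene-level gene-sharing networks from the
    binary presence/absence matrix with normalized edge weights and
    connected-component extraction; clusters prophage nucleotide
    sequences into species-level groups by greedy incremental assignment
    at an identity and length-difference cutoff; screens prophages
    against similarity hit tables for taxonomy, virulence factors and
    gut-phageome membership tiers; flags integrase genes; and reduces
    spot-assay lysis matrices to host ranges, pairwise susceptibility
    tables and phage-cocktail coverage. A seeded synthetic-data
    generator with planted phage families makes every stage testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
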