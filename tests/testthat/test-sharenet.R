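make_assignments <- function(...) {
  # ... = named vectors: genome id -> cluster ids of its genes
  genomes <- list(...)
  gene_id <- character(0); genome_id <- character(0); cluster <- integer(0)
  for (g in names(genomes)) {
    for (cl in genomes[[g]]) {
      gene_id <- c(gene_id, sprintf("%s_c%d_%d", g, cl, length(gene_id)))
      genome_id <- c(genome_id, g)
      cluster <- c(cluster, cl)
    }
  }
  list(assignments = data.frame(gene_id = gene_id, cluster_id = cluster),
       map = data.frame(gene_id = gene_id, genome_id = genome_id))
}

test_that("presence matrix binarizes multiplicity and records row sums", {
  x <- make_assignments(G1 = c(0, 1), G2 = c(1, 2))
  P <- build_presence_matrix(x$assignments, x$map)
  expect_equal(dim(P), c(2L, 3L))
  expect_equal(unname(P["G1", ]), c(1L, 1L, 0L))
  expect_equal(unname(P["G2", ]), c(0L, 1L, 1L))
  expect_equal(unname(rowSums(P)), c(2, 2))
  # duplicate cluster membership still gives a single 1
  y <- make_assignments(G1 = c(0, 0, 1))
  P2 <- build_presence_matrix(y$assignments, y$map)
  expect_equal(unname(P2["G1", ]), c(1L, 1L))
  # unknown genome is a data error
  bad_map <- x$map[-1, ]
  expect_error(build_presence_matrix(x$assignments, bad_map), "data error")
  expect_equal(dim(build_presence_matrix(
    data.frame(gene_id = character(0), cluster_id = integer(0)),
    x$map)), c(0L, 0L))
})

test_that("genome adjacency equals explicit set intersections", {
  x <- make_assignments(G1 = c(0, 1), G2 = c(1, 2), G3 = c(3))
  P <- build_presence_matrix(x$assignments, x$map)
  ga <- genome_adjacency(P)
  expect_equal(ga$S["G1", "G2"], 1)
  expect_equal(ga$A["G1", "G2"], 1)
  expect_equal(ga$S["G1", "G3"], 0)
  expect_equal(ga$A["G1", "G3"], 0)
  # random matrix against the brute-force oracle
  set.seed(41)
  R <- matrix(rbinom(20 * 60, 1, 0.15), 20, 60,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  ga2 <- genome_adjacency(R)
  expect_equal(unname(ga2$S), unname(shared_counts_oracle(R)))
  expect_true(isSymmetric(ga2$S))
  expect_true(all(diag(ga2$A) == 0))
})

test_that("gene adjacency mirrors genome adjacency on the transpose", {
  x <- make_assignments(G1 = c(0, 1), G2 = c(2))
  P <- build_presence_matrix(x$assignments, x$map)
  gaa <- gene_adjacency(P)
  expect_equal(gaa$A["0", "1"], 1)   # co-resident in G1
  expect_equal(gaa$A["0", "2"], 0)   # never co-resident
  set.seed(42)
  R <- matrix(rbinom(15 * 40, 1, 0.2), 15, 40,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("c%02d", 1:40)))
  expect_equal(unname(gene_adjacency(R)$S),
               unname(shared_counts_oracle(t(R))))
})

test_that("edge weights follow w = s / (l_a * l_b) with the w bound", {
  x <- make_assignments(G1 = c(0, 1, 2), G2 = c(1, 2, 3))
  P <- build_presence_matrix(x$assignments, x$map)
  ga <- genome_adjacency(P)
  e <- edge_weights(ga$S, ga$l)
  expect_equal(e$s, 2L)
  expect_equal(e$w, 2 / 9)
  # identical genomes: w = 1 / l
  y <- make_assignments(A = c(0, 1), B = c(0, 1))
  Py <- build_presence_matrix(y$assignments, y$map)
  gy <- genome_adjacency(Py)
  expect_equal(edge_weights(gy$S, gy$l)$w, 1 / 2)
  # simulated catalog: bound w <= 1/max(l_a, l_b) and s <= min(l)
  sim <- mosaic_sim_fixture()
  pan <- cluster_genes(sim$genes)
  Ps <- build_presence_matrix(pan$assignments, sim$gene_table)
  gs <- genome_adjacency(Ps)
  es <- edge_weights(gs$S, gs$l)
  expect_true(all(es$s >= 1))
  expect_true(all(es$s <= pmin(gs$l[es$genome_a], gs$l[es$genome_b])))
  expect_true(all(es$w <= 1 / pmax(gs$l[es$genome_a], gs$l[es$genome_b]) +
                    1e-12))
})

test_that("edge filtering is strict in minw mode and >= in fraction mode", {
  e <- data.frame(genome_a = c("A", "B"), genome_b = c("B", "C"),
                  s = c(2L, 3L), w = c(2 / 9, 0.25))
  expect_equal(nrow(filter_edges(e, minw = 0)), 2L)
  expect_equal(nrow(filter_edges(e, minw = 2 / 9)), 1L)  # strict >
  expect_equal(nrow(filter_edges(e, minw = 0.25)), 0L)
  l <- c(A = 3, B = 9, C = 10)
  # fraction: s / min(l) >= f, inclusive
  kept <- filter_edges(e, mode = "fraction", fraction = 2 / 3, l = l)
  expect_equal(kept$genome_a, "A")
  expect_error(filter_edges(e, mode = "fraction"), "data error")
})

test_that("edge count is monotone non-increasing in minw", {
  sim <- mosaic_sim_fixture()
  pan <- cluster_genes(sim$genes)
  P <- build_presence_matrix(pan$assignments, sim$gene_table)
  ga <- genome_adjacency(P)
  e <- edge_weights(ga$S, ga$l)
  prev <- Inf
  for (minw in c(0, 0.005, 0.01, 0.02, 0.05, 0.2)) {
    n <- nrow(filter_edges(e, minw))
    expect_lte(n, prev)
    prev <- n
  }
  # component count is non-decreasing along the same sweep
  prev_comp <- 0
  for (minw in c(0, 0.005, 0.01, 0.02, 0.05, 0.2)) {
    net <- build_network(P, minw = minw)
    n_comp <- max(net$components)
    expect_gte(n_comp, prev_comp)
    prev_comp <- n_comp
  }
})

test_that("component labels match a BFS oracle and ignore edge order", {
  expect_equal(unname(connected_components(c("a", "b", "c"),
                                           data.frame(genome_a = character(0),
                                                      genome_b = character(0)))),
               1:3)
  path <- data.frame(genome_a = c("a", "b"), genome_b = c("b", "c"))
  expect_equal(unname(connected_components(c("a", "b", "c"), path)),
               c(1L, 1L, 1L))
  expect_error(connected_components(c("a", "b"), path), "data error")
  set.seed(29)
  nodes <- sprintf("v%03d", 1:100)
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < 0.02
  edges <- data.frame(genome_a = pairs[keep, 1], genome_b = pairs[keep, 2])
  got <- connected_components(nodes, edges)
  want <- bfs_components_oracle(nodes, edges)
  expect_equal(got[nodes], want[nodes])
  # invariance to edge permutation
  perm <- edges[sample(nrow(edges)), ]
  expect_equal(connected_components(nodes, perm)[nodes], got[nodes])
})

test_that("network export round-trips its own edge list", {
  x <- make_assignments(G1 = c(0, 1), G2 = c(1, 2), G3 = c(5))
  P <- build_presence_matrix(x$assignments, x$map)
  net <- build_network(P, minw = 0)
  dir <- withr::local_tempdir()
  export_network(net, dir, taxonomy = c(G1 = "Myoviruses"))
  edges <- read.delim(file.path(dir, "edges.tsv"))
  expect_equal(edges$genome_a, net$edges$genome_a)
  expect_equal(edges$w, net$edges$w)
  sif <- readLines(file.path(dir, "network.sif"))
  expect_length(sif, nrow(net$edges))
  expect_match(sif[1], "^G1\tsg\tG2$")
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  expect_setequal(nodes$id, c("G1", "G2", "G3"))
  expect_equal(nodes$taxonomy[nodes$id == "G1"], "Myoviruses")
  expect_equal(nodes$taxonomy[nodes$id == "G2"], "Unknown")
  # empty edge set still writes a header-only TSV
  net0 <- build_network(P, minw = 1)
  export_network(net0, dir)
  expect_equal(nrow(read.delim(file.path(dir, "edges.tsv"))), 0L)
})

test_that("planted families surface as network components at minw = 0", {
  res <- pipeline_fixture()
  expect_equal(max(res$network$components), 3L)
  fam <- res$sim$truth$genomes$family[
    match(res$network$nodes, res$sim$truth$genomes$genome_id)]
  expect_equal(length(unique(paste(fam, res$network$components))), 3L)
})
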