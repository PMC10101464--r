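#' Build the genome x gene-cluster presence/absence matrix
#'
#' Entry `P[i, j]` is 1 iff genome `i` carries at least one gene assigned to
#' cluster `j` (multiplicity collapses to 1). The matrix is the adjacency of
#' the bipartite genome-gene network; its row sums `l_i` give each genome's
#' size in gene clusters. All-zero columns are dropped.
#'
#' @param assignments data.frame (gene_id, cluster_id) from
#'   [mcl_cluster()].
#' @param gene_map data.frame (gene_id, genome_id) mapping every gene to its
#'   genome, e.g. the simulator's gene table.
#' @return Binary integer matrix with genome ids as row names and cluster
#'   ids (as character) as column names.
#' @export
build_presence_matrix <- function(assignments, gene_map) {
  if (nrow(assignments) == 0L)
    return(matrix(0L, 0, 0))
  genome <- gene_map$genome_id[match(assignments$gene_id, gene_map$gene_id)]
  if (anyNA(genome))
    stop("data error: gene(s) with unknown genome: ",
         paste(utils::head(assignments$gene_id[is.na(genome)], 5),
               collapse = ", "))
  genomes <- unique(genome)
  clusters <- sort(unique(assignments$cluster_id))
  P <- matrix(0L, length(genomes), length(clusters),
              dimnames = list(genomes, as.character(clusters)))
  P[cbind(match(genome, genomes),
          match(assignments$cluster_id, clusters))] <- 1L
  P <- P[, colSums(P) > 0, drop = FALSE]
  P
}

#' Genome-level shared-gene counts and adjacency
#'
#' Computes `S = P P^T`, whose entry `S[i, k]` counts the gene clusters
#' shared by genomes `i` and `k`, and the unweighted adjacency
#' `A = sign(S)` with the diagonal excluded: two genomes are connected iff
#' they share any gene cluster.
#'
#' @param P presence/absence matrix from [build_presence_matrix()].
#' @return list with `S` (integer matrix), `A` (binary matrix, zero
#'   diagonal) and `l` (row sums of `P`).
#' @export
genome_adjacency <- function(P) {
  S <- P %*% t(P)
  A <- sign(S)
  diag(A) <- 0L
  list(S = S, A = A, l = rowSums(P))
}

#' Gene-level co-occurrence adjacency
#'
#' Transposed analogue of [genome_adjacency()]: `sign(P^T P)` connects two
#' gene clusters iff they co-occur in at least one genome.
#'
#' @param P presence/absence matrix.
#' @return list with `S`, `A` and `l` (column sums of `P`).
#' @export
gene_adjacency <- function(P) {
  S <- t(P) %*% P
  A <- sign(S)
  diag(A) <- 0L
  list(S = S, A = A, l = colSums(P))
}

#' Normalized network edges from shared-gene counts
#'
#' For every genome pair sharing `s >= 1` gene clusters, emits an edge with
#' weight `w = s / (l_a * l_b)` where `l_i` is genome i's gene-cluster
#' count. Since `s <= min(l_a, l_b)`, `w <= 1 / max(l_a, l_b)`.
#'
#' @param S shared-count matrix from [genome_adjacency()].
#' @param l genome sizes (row sums of `P`), named by genome.
#' @return data.frame (genome_a, genome_b, s, w), each unordered pair once.
#' @export
edge_weights <- function(S, l) {
  ids <- rownames(S)
  stopifnot(!is.null(ids), all(ids %in% names(l)))
  ut <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L)
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      s = integer(0), w = numeric(0)))
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  s <- S[ut]
  data.frame(genome_a = a, genome_b = b, s = as.integer(s),
             w = s / (l[a] * l[b]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter network edges by weight or shared-gene fraction
#'
#' Default rule retains an edge iff `w > minw` (strict inequality).
#' The alternative `"fraction"` rule retains an edge iff
#' `s / min(l_a, l_b) >= fraction`, i.e. the two genomes share at least
#' that fraction of the smaller genome's genic content.
#'
#' @param edges data.frame from [edge_weights()].
#' @param minw weight threshold for the default rule (>= 0).
#' @param mode `"minw"` (default) or `"fraction"`.
#' @param fraction shared-content fraction for `"fraction"` mode.
#' @param l genome sizes, required for `"fraction"` mode.
#' @return The retained edge rows.
#' @export
filter_edges <- function(edges, minw = 0, mode = c("minw", "fraction"),
                         fraction = 0.30, l = NULL) {
  mode <- match.arg(mode)
  if (minw < 0) stop("validation error: minw must be >= 0")
  if (mode == "minw")
    return(edges[edges$w > minw, , drop = FALSE])
  if (is.null(l)) stop("data error: 'fraction' mode needs genome sizes 'l'")
  lmin <- pmin(l[edges$genome_a], l[edges$genome_b])
  edges[edges$s / lmin >= fraction, , drop = FALSE]
}

#' Connected components of the prophage network
#'
#' Labels every node with the id of its connected component under the
#' retained edges. Labels are canonicalized so that components are numbered
#' 1, 2, ... in order of their smallest member id; the labeling is therefore
#' invariant to edge-list permutation.
#'
#' @param nodes character vector of all node ids (isolated nodes allowed).
#' @param edges data.frame with columns `genome_a`, `genome_b`.
#' @return Named integer vector of component labels.
#' @export
connected_components <- function(nodes, edges) {
  bad <- setdiff(c(edges$genome_a, edges$genome_b), nodes)
  if (length(bad))
    stop("data error: edge endpoint(s) not in nodes: ",
         paste(utils::head(bad, 5), collapse = ", "))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$genome_a, edges$genome_b))
  memb <- igraph::components(g)$membership
  # canonicalize: components ordered by their smallest member id
  smallest <- tapply(names(memb), memb, min)
  rank <- match(memb, as.integer(names(sort(smallest))))
  stats::setNames(rank, names(memb))
}

#' Assemble a filtered prophage network
#'
#' Runs the full genome-network stage: shared counts, `w` weighting, edge
#' filtering and component labeling.
#'
#' @param P presence/absence matrix.
#' @inheritParams filter_edges
#' @return list of class `phage_network` with `nodes`, `edges` (retained),
#'   `components` (named labels), `l`, and the filter settings.
#' @export
build_network <- function(P, minw = 0, mode = c("minw", "fraction"),
                          fraction = 0.30) {
  mode <- match.arg(mode)
  ga <- genome_adjacency(P)
  edges <- edge_weights(ga$S, ga$l)
  kept <- filter_edges(edges, minw = minw, mode = mode,
                       fraction = fraction, l = ga$l)
  comp <- connected_components(rownames(P), kept)
  structure(list(nodes = rownames(P), edges = kept, components = comp,
                 l = ga$l, minw = minw, mode = mode, fraction = fraction),
            class = "phage_network")
}

#' Export a network as edge list, SIF and node attribute table
#'
#' Writes `edges.tsv` (genome_a, genome_b, s, w), `network.sif`
#' (`a<TAB>sg<TAB>b`, one line per edge) and `nodes.tsv` (id, component, l,
#' taxonomy) under `dir`. All files are tab-separated UTF-8 with LF
#' endings, loadable by Cytoscape.
#'
#' @param network a `phage_network` from [build_network()].
#' @param dir output directory.
#' @param taxonomy optional named character vector of node taxonomy labels;
#'   missing nodes get "Unknown".
#' @return `dir`, invisibly.
#' @export
export_network <- function(network, dir, taxonomy = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(network$edges, file.path(dir, "edges.tsv"))
  sif <- sprintf("%s\tsg\t%s", network$edges$genome_a,
                 network$edges$genome_b)
  con <- file(file.path(dir, "network.sif"), "wb")
  writeLines(sif, con, sep = "\n")
  close(con)
  tax <- if (is.null(taxonomy)) rep("Unknown", length(network$nodes))
         else ifelse(network$nodes %in% names(taxonomy),
                     taxonomy[network$nodes], "Unknown")
  nodes <- data.frame(id = network$nodes,
                      component = network$components[network$nodes],
                      l = network$l[network$nodes],
                      taxonomy = tax, stringsAsFactors = FALSE)
  write_tsv(nodes, file.path(dir, "nodes.tsv"))
  invisible(dir)
}
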