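#' Markov clustering parameters
#'
#' @param inflation elementwise power applied after each expansion;
#'   larger values give finer clusters. Default 2.
#' @param expansion matrix power of the expansion step. Default 2.
#' @param prune_threshold entries below this are zeroed after inflation.
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   last iterate is used.
#' @param tol convergence tolerance on the max absolute change.
#' @return list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, expansion = 2L,
                       prune_threshold = 1e-5, max_iter = 100L,
                       tol = 1e-6) {
  if (inflation <= 1) stop("validation error: inflation must be > 1")
  if (max_iter < 1L) stop("validation error: max_iter must be >= 1")
  if (tol <= 0) stop("validation error: tol must be > 0")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_params")
}

#' Local alignment score between two nucleotide sequences
#'
#' Smith-Waterman local alignment score with match +5, mismatch -4, gap
#' opening -8 and gap extension -2 (a gap of length L costs 8 + 2L). The
#' self score of a length-L sequence is 5L, which anchors the minbit
#' normalization. Scores are floored at 0 (the empty local alignment).
#'
#' @param seq_a,seq_b nucleotide sequences (character scalars).
#' @return Non-negative alignment score.
#' @export
pair_score <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("validation error: sequences must be non-empty")
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                baseOnly = TRUE)
  s <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "local",
                                     substitutionMatrix = m,
                                     gapOpening = 8, gapExtension = 2,
                                     scoreOnly = TRUE)
  max(0, s)
}

# k-mer set of a sequence (character scalar), used by the prescreens
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

shares_kmer <- function(set_a, set_b) {
  length(set_a) > 0L && length(set_b) > 0L && any(set_a %in% set_b)
}

#' All-vs-all similarity edges with minbit normalization
#'
#' Scores every gene pair that shares at least one k-mer (the prescreen
#' cannot remove true homologs at the identity levels this package
#' targets), and normalizes each score by the smaller of the two self
#' scores: `minbit = score / min(5 * len_a, 5 * len_b)`, a symmetric
#' similarity in `[0, 1]`.
#'
#' @param genes named character vector of gene sequences.
#' @param k prescreen word length.
#' @return data.frame (gene_a, gene_b, score, minbit) with `gene_a < gene_b`
#'   lexicographically; zero-score pairs are omitted.
#' @export
gene_similarity_edges <- function(genes, k = 8L) {
  stopifnot(!is.null(names(genes)), !anyDuplicated(names(genes)))
  n <- length(genes)
  if (n < 2L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), minbit = numeric(0)))
  kms <- lapply(genes, kmer_set, k = k)
  self <- 5 * nchar(genes)
  out <- vector("list", n * (n - 1L) / 2L)
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                baseOnly = TRUE)
  idx <- 0L
  for (i in seq_len(n - 1L)) {
    js <- which(vapply((i + 1L):n, function(j) shares_kmer(kms[[i]], kms[[j]]),
                       logical(1))) + i
    if (!length(js)) next
    sc <- pmax(0, Biostrings::pairwiseAlignment(
      rep(genes[[i]], length(js)),
      Biostrings::DNAStringSet(unname(genes[js])),
      type = "local", substitutionMatrix = m,
      gapOpening = 8, gapExtension = 2, scoreOnly = TRUE))
    keep <- sc > 0
    if (!any(keep)) next
    idx <- idx + 1L
    out[[idx]] <- data.frame(
      gene_a = names(genes)[i], gene_b = names(genes)[js][keep],
      score = sc[keep],
      minbit = sc[keep] / pmin(self[[i]], self[js][keep]),
      stringsAsFactors = FALSE)
  }
  if (idx == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), minbit = numeric(0)))
  res <- do.call(rbind, out[seq_len(idx)])
  swap <- res$gene_a > res$gene_b
  tmp <- res$gene_a[swap]; res$gene_a[swap] <- res$gene_b[swap]
  res$gene_b[swap] <- tmp
  rownames(res) <- NULL
  res
}

#' Filter similarity edges by minbit
#'
#' Keeps edges with `minbit >= threshold`. Raising the threshold never adds
#' edges (monotone filter).
#'
#' @param edges data.frame from [gene_similarity_edges()].
#' @param threshold minbit cutoff, default 0.35.
#' @return The retained rows.
#' @export
minbit_filter <- function(edges, threshold = 0.35) {
  if (!all(c("gene_a", "gene_b", "minbit") %in% names(edges)))
    stop("data error: edges must carry gene_a, gene_b and minbit")
  if (any(is.na(edges$minbit)))
    stop("data error: missing minbit (self score unavailable?)")
  edges[edges$minbit >= threshold, , drop = FALSE]
}

# --- MCL internals ----------------------------------------------------------

mcl_add_self_loops <- function(adj) {
  loop <- apply(adj, 2, max)
  loop[loop == 0] <- 1          # isolated nodes get a unit loop
  diag(adj) <- loop
  adj
}

mcl_normalize <- function(m) {
  cs <- colSums(m)
  if (any(cs == 0)) stop("data error: zero column encountered in MCL matrix")
  sweep(m, 2, cs, "/")
}

mcl_inflate <- function(m, inflation, prune_threshold) {
  m <- m^inflation
  m[m < prune_threshold] <- 0
  mcl_normalize(m)
}

# Read clusters off a converged MCL matrix: attractors are nodes with
# positive diagonal mass; each node is assigned to the attractor holding
# the largest mass in its column (ties to the lowest attractor index).
mcl_interpret <- function(m, prune_threshold) {
  n <- nrow(m)
  attractors <- which(diag(m) > prune_threshold)
  if (!length(attractors)) attractors <- seq_len(n)
  owner <- integer(n)
  for (j in seq_len(n)) {
    mass <- m[attractors, j]
    if (all(mass <= 0)) owner[j] <- j  # orphan: own singleton
    else owner[j] <- attractors[which.max(mass)]
  }
  # attractors mutually supporting each other collapse to one cluster
  owner[attractors] <- vapply(attractors, function(a) {
    mass <- m[attractors, a]
    attractors[which.max(mass)]
  }, integer(1))
  # resolve chains among attractor owners to a fixed point
  repeat {
    nxt <- owner[owner]
    if (identical(nxt, owner)) break
    owner <- nxt
  }
  match(owner, sort(unique(owner))) - 1L
}

#' Markov clustering (MCL) of a weighted similarity graph
#'
#' From-scratch MCL over a non-negative, undirected similarity graph: adds a
#' self loop per node equal to its maximum incident weight, column-normalizes
#' to a stochastic matrix, then alternates expansion (matrix power),
#' inflation (elementwise power and renormalization) and pruning of entries
#' below `prune_threshold` until the maximum absolute change falls below
#' `tol` or `max_iter` is reached. Clusters are read off the attractor rows'
#' supports; every node is assigned, with ties broken toward the lowest node
#' index. Disconnected components can never merge.
#'
#' @param edges data.frame (gene_a, gene_b, weight) or the output of
#'   [gene_similarity_edges()] / [minbit_filter()] (the `minbit` column is
#'   used as the weight).
#' @param nodes optional character vector of all node ids, so that genes
#'   with no retained edges still appear (as singletons).
#' @param params an [mcl_params()].
#' @return data.frame (gene_id, cluster_id) — a partition with dense integer
#'   cluster ids from 0, ordered by first appearance over node order.
#' @export
mcl_cluster <- function(edges, nodes = NULL, params = mcl_params()) {
  stopifnot(inherits(params, "mcl_params"))
  wcol <- if ("weight" %in% names(edges)) "weight" else "minbit"
  if (nrow(edges) > 0 && !all(c("gene_a", "gene_b") %in% names(edges)))
    stop("data error: edges must carry gene_a and gene_b")
  if (nrow(edges) > 0 && any(edges[[wcol]] < 0))
    stop("validation error: negative edge weight")
  ids <- unique(c(nodes, edges$gene_a, edges$gene_b))
  if (!length(ids))
    return(data.frame(gene_id = character(0), cluster_id = integer(0)))
  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    ia <- match(edges$gene_a, ids); ib <- match(edges$gene_b, ids)
    w <- edges[[wcol]]
    adj[cbind(ia, ib)] <- pmax(adj[cbind(ia, ib)], w)
    adj[cbind(ib, ia)] <- pmax(adj[cbind(ib, ia)], w)
  }
  diag(adj) <- 0
  m <- mcl_normalize(mcl_add_self_loops(adj))
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    prev <- m
    ex <- m
    for (p in seq_len(params$expansion - 1L)) ex <- ex %*% m
    m <- mcl_inflate(ex, params$inflation, params$prune_threshold)
    if (max(abs(m - prev)) < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iter,
            " iterations; using last iterate")
  cl <- mcl_interpret(m, params$prune_threshold)
  # dense ids in order of first appearance
  cl <- match(cl, unique(cl)) - 1L
  data.frame(gene_id = ids, cluster_id = cl, stringsAsFactors = FALSE)
}

#' Cluster genes into homolog families
#'
#' The full pan-genome stage: all-vs-all similarity scoring, minbit
#' filtering at `minbit` (default 0.35) and MCL at the requested inflation.
#' Genes left without any retained edge become singleton clusters.
#'
#' @param genes named character vector of gene sequences.
#' @param minbit minbit cutoff.
#' @param params an [mcl_params()].
#' @param k prescreen word length passed to [gene_similarity_edges()].
#' @return list with `assignments` (gene_id, cluster_id) and `edges` (the
#'   minbit-filtered similarity edges).
#' @export
cluster_genes <- function(genes, minbit = 0.35, params = mcl_params(),
                          k = 8L) {
  edges <- minbit_filter(gene_similarity_edges(genes, k = k), minbit)
  assignments <- mcl_cluster(edges, nodes = names(genes), params = params)
  list(assignments = assignments, edges = edges)
}
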