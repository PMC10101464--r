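# Independent brute-force oracles. These deliberately re-derive results by
# the most direct method available (full dynamic programming, BFS,
# exhaustive enumeration) and stay independent of the package code paths
# they check.

# Smith-Waterman local alignment score, full DP with affine gaps:
# a gap of length L costs gap_open + L * gap_extend.
sw_score_oracle <- function(a, b, match = 5, mismatch = -4,
                            gap_open = 8, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  Fm <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      Fm[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                      Fm[i - 1, j] - gap_extend)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Glocal (pattern-global, subject-local) alignment score, full DP with
# affine gaps; the pattern `a` must be consumed entirely, subject flanks
# are free.
glocal_score_oracle <- function(a, b, match = 2, mismatch = -3,
                                gap_open = 5, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # a_i aligned to b_j
  X <- matrix(NEG, n + 1, m + 1)   # gap in subject (pattern consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in pattern (subject consumed)
  M[1, ] <- 0                      # free leading subject flank
  for (i in 2:(n + 1)) {
    X[i, 1] <- max(M[i - 1, 1] - gap_open - gap_extend,
                   X[i - 1, 1] - gap_extend)
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, ], X[n + 1, ])      # free trailing subject flank
}

# Connected-component labels by BFS, canonicalized like the package:
# components numbered by their smallest member id.
bfs_components_oracle <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges$genome_a[r]; b <- edges$genome_b[r]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  label <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  comp_min <- character(0)
  k <- 0L
  for (v in nodes) {
    if (!is.na(label[v])) next
    k <- k + 1L
    queue <- v
    members <- character(0)
    label[v] <- k
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      members <- c(members, u)
      for (wn in adj[[u]]) {
        if (is.na(label[wn])) { label[wn] <- k; queue <- c(queue, wn) }
      }
    }
    comp_min[k] <- min(members)
  }
  rank <- match(label, order(comp_min))
  stats::setNames(rank, nodes)
}

# Shared-gene counts by explicit set intersection over row pairs.
shared_counts_oracle <- function(P) {
  n <- nrow(P)
  S <- matrix(0L, n, n, dimnames = dimnames(P)[c(1, 1)])
  sets <- lapply(seq_len(n), function(i) which(P[i, ] > 0))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  S
}

# Dense MCL iteration run a fixed number of times; clusters read as the
# connected components of the (symmetrized) support of the limit matrix.
mcl_oracle <- function(adj, inflation = 2, iters = 200, prune = 1e-5) {
  loop <- apply(adj, 2, max)
  loop[loop == 0] <- 1
  diag(adj) <- loop
  m <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    m <- m %*% m
    m <- m^inflation
    m[m < prune] <- 0
    m <- sweep(m, 2, colSums(m), "/")
  }
  supp <- (m > prune) | t(m > prune)
  idx <- which(supp & upper.tri(supp), arr.ind = TRUE)
  ids <- rownames(adj)
  edges <- data.frame(genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  bfs_components_oracle(ids, edges)
}

# Canonical form of a partition (a named label vector): list of sorted
# member vectors, sorted by first member, for label-free comparison.
canonical_partition <- function(labels) {
  parts <- split(names(labels), labels)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# Independent greedy clustering applying the same join rule with its own
# scan (used against greedy_cluster on small inputs).
greedy_oracle <- function(sequences, identity_threshold = 0.8,
                          length_cutoff = 0.8, word = 4L) {
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  words <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - word + 1L), word:n))
  }
  reps <- integer(0)
  member_of <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      if (nchar(sequences[[i]]) / nchar(sequences[[r]]) < length_cutoff) next
      if (!any(words(sequences[[i]]) %in% words(sequences[[r]]))) next
      ident <- prophagenet::pairwise_identity(sequences[[i]], sequences[[r]])
      if (ident >= identity_threshold) {
        member_of[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); member_of[i] <- length(reps) }
  }
  stats::setNames(member_of, names(sequences))
}

# Mutate a sequence at a fixed per-site substitution rate (test-local).
mutate_oracle <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  paste(bases, collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
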