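#' Configuration for greedy species-level sequence clustering
#'
#' Defaults mirror common nucleotide est-clustering practice: 80% identity,
#' 80% length-difference cutoff, word length 4.
#'
#' @param identity_threshold minimum identity of a member to its cluster
#'   representative, in (0, 1].
#' @param length_diff_cutoff minimum shorter/longer length ratio, in (0, 1].
#' @param word_length prescreen word length (>= 2).
#' @param band_width nominal alignment band half-width; retained for
#'   interface compatibility — alignments at package scale run full dynamic
#'   programming in compiled code.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(identity_threshold = 0.80,
                           length_diff_cutoff = 0.80,
                           word_length = 4L, band_width = 32L) {
  for (f in c(identity_threshold, length_diff_cutoff))
    if (f <= 0 || f > 1)
      stop("validation error: thresholds must lie in (0, 1]")
  if (word_length < 2L)
    stop("validation error: word_length must be >= 2")
  structure(list(identity_threshold = identity_threshold,
                 length_diff_cutoff = length_diff_cutoff,
                 word_length = as.integer(word_length),
                 band_width = as.integer(band_width)),
            class = "cluster_config")
}

#' Pairwise nucleotide identity of the shorter sequence within the longer
#'
#' Aligns the shorter sequence globally against the best-matching region of
#' the longer one (glocal alignment; match +2, mismatch -3, gap opening 5,
#' gap extension 2) and returns `matches / length(shorter)`.
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @param cfg a [cluster_config()] (unused by the unbanded implementation;
#'   kept for interface stability).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, cfg = cluster_config()) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("validation error: sequences must be non-empty")
  if (nchar(seq_a) > nchar(seq_b)) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global-local",
                                      substitutionMatrix = m,
                                      gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(pa) / nchar(seq_a)
}

#' Greedy incremental clustering of prophage sequences
#'
#' Sequences are sorted by length descending (ties by id ascending) and
#' scanned in order. A sequence joins the first existing cluster whose
#' representative passes all of: (a) length ratio shorter/longer >=
#' `length_diff_cutoff`, (b) at least one shared word of `word_length`,
#' (c) identity >= `identity_threshold` ([pairwise_identity()]). Otherwise
#' it founds a new cluster and becomes its representative; representatives
#' are therefore always the longest member of their cluster.
#'
#' @param sequences named character vector (>= 1 sequence, unique ids).
#' @param cfg a [cluster_config()].
#' @return list of clusters, each a list with `cluster_id` (0-based),
#'   `representative_id` and `members` (data.frame: seq_id,
#'   identity_to_rep, length).
#' @export
greedy_cluster <- function(sequences, cfg = cluster_config()) {
  if (length(sequences) < 1L)
    stop("validation error: need at least one sequence")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("data error: sequences must carry unique ids")
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- integer(0)                     # indices of representatives
  rep_words <- list()
  membership <- integer(length(sequences))
  identity <- numeric(length(sequences))
  for (i in seq_along(sequences)) {
    words_i <- kmer_set(sequences[[i]], cfg$word_length)
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      ratio <- nchar(sequences[[i]]) / nchar(sequences[[r]])
      if (ratio < cfg$length_diff_cutoff) next
      if (!shares_kmer(words_i, rep_words[[ci]])) next
      ident <- pairwise_identity(sequences[[i]], sequences[[r]], cfg)
      if (ident >= cfg$identity_threshold) {
        membership[i] <- ci
        identity[i] <- ident
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rep_words[[length(reps)]] <- words_i
      membership[i] <- length(reps)
      identity[i] <- 1.0
    }
  }
  lapply(seq_along(reps), function(ci) {
    idx <- which(membership == ci)
    list(cluster_id = ci - 1L,
         representative_id = names(sequences)[reps[ci]],
         members = data.frame(
           seq_id = names(sequences)[idx],
           identity_to_rep = identity[idx],
           length = nchar(sequences[idx]),
           row.names = NULL, stringsAsFactors = FALSE))
  })
}

#' Write clusters in .clstr-style text
#'
#' One `>Cluster N` header per cluster; member lines read
#' `i<TAB><len>nt, ><id>... at +/<pct>%` with the percentage printed to two
#' decimals, and the representative line ends with `*` instead.
#'
#' @param clusters output of [greedy_cluster()].
#' @param path output file; omit to return the lines invisibly only.
#' @return Character vector of lines, invisibly.
#' @export
write_clstr <- function(clusters, path = NULL) {
  lines <- character(0)
  for (cl in clusters) {
    lines <- c(lines, sprintf(">Cluster %d", cl$cluster_id))
    for (j in seq_len(nrow(cl$members))) {
      m <- cl$members[j, ]
      tail <- if (m$seq_id == cl$representative_id) "*"
              else sprintf("at +/%.2f%%", 100 * m$identity_to_rep)
      lines <- c(lines, sprintf("%d\t%dnt, >%s... %s",
                                j - 1L, m$length, m$seq_id, tail))
    }
  }
  if (!is.null(path)) {
    con <- file(path, "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
  }
  invisible(lines)
}

#' Parse .clstr-style text back into cluster membership
#'
#' @param lines character vector of lines, or a file path.
#' @return data.frame (cluster_id, seq_id, length, identity_to_rep,
#'   is_representative).
#' @export
read_clstr <- function(lines) {
  if (length(lines) == 1L && file.exists(lines))
    lines <- readLines(lines)
  out <- list()
  current <- NA_integer_
  for (ln in lines) {
    if (startsWith(ln, ">Cluster")) {
      current <- as.integer(sub("^>Cluster ", "", ln))
    } else if (nzchar(ln)) {
      len <- as.integer(sub("^\\d+\t(\\d+)nt,.*$", "\\1", ln))
      id <- sub("^[^>]*>(.*)\\.\\.\\. .*$", "\\1", ln)
      is_rep <- grepl("\\*\\s*$", ln)
      ident <- if (is_rep) 1.0
               else as.numeric(sub("^.*at \\+/([0-9.]+)%$", "\\1", ln)) / 100
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = current, seq_id = id, length = len,
        identity_to_rep = ident, is_representative = is_rep,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = integer(0), seq_id = character(0),
                      length = integer(0), identity_to_rep = numeric(0),
                      is_representative = logical(0)))
  do.call(rbind, out)
}

#' Summarize a set of sequence clusters
#'
#' @param clusters output of [greedy_cluster()].
#' @return list with `n_clusters`, `n_singletons`, `singleton_fraction`,
#'   `largest_size` and `rep_lengths` (data.frame: cluster_id, size,
#'   rep_length) for cluster-size/length association checks.
#' @export
cluster_summary <- function(clusters) {
  if (!length(clusters)) stop("validation error: no clusters")
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  rep_len <- vapply(clusters, function(cl) {
    cl$members$length[cl$members$seq_id == cl$representative_id][1]
  }, integer(1))
  list(n_clusters = length(clusters),
       n_singletons = sum(sizes == 1L),
       singleton_fraction = sum(sizes == 1L) / length(clusters),
       largest_size = max(sizes),
       rep_lengths = data.frame(
         cluster_id = vapply(clusters, `[[`, integer(1), "cluster_id"),
         size = sizes, rep_length = rep_len))
}

#' Write cluster representatives to FASTA
#'
#' @param clusters output of [greedy_cluster()].
#' @param sequences the named sequence vector that was clustered.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_representatives <- function(clusters, sequences, path) {
  ids <- vapply(clusters, `[[`, character(1), "representative_id")
  write_fasta(sequences[ids], path)
}
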