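#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that tolerates wrapped
#' and unwrapped records and CRLF endings; names are truncated at the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA with 70-column wrapping
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "wb")  # LF endings on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    chunks <- substring(seqs[[i]],
                        seq(1L, nchar(seqs[[i]]), 70L),
                        pmin(seq(1L, nchar(seqs[[i]]), 70L) + 69L,
                             nchar(seqs[[i]])))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Read a BLAST tabular hit table
#'
#' Reads headerless tab-separated hit tables in the standard 12-column
#' outfmt-6 order (qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore); an optional 13th column is taken as query
#' coverage (`qcovs`), a 14th as subject coverage and a 15th as a subject
#' taxonomy label.
#'
#' @param path tab-separated hit table.
#' @return data.frame with the column names used throughout the annotation
#'   screens (see [gen_hit_table()] for the full set).
#' @export
read_blast_tab <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading '", path, "': ",
                             conditionMessage(e)))
  if (nrow(raw) == 0L) return(empty_hit_table())
  if (ncol(raw) < 12L)
    stop("parse error: expected >= 12 tab-separated columns, found ",
         ncol(raw))
  names(raw)[1:12] <- c("query_id", "subject_id", "percent_identity",
                        "alignment_length", "mismatches", "gap_openings",
                        "q_start", "q_end", "s_start", "s_end",
                        "evalue", "bitscore")
  if (ncol(raw) >= 13L) names(raw)[13] <- "query_coverage"
  if (ncol(raw) >= 14L) names(raw)[14] <- "subject_coverage"
  if (ncol(raw) >= 15L) names(raw)[15] <- "subject_taxonomy"
  num_cols <- c("percent_identity", "evalue", "bitscore",
                intersect(c("query_coverage", "subject_coverage"),
                          names(raw)))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad))
      stop("parse error: non-numeric '", cn, "' at line ", bad[1])
    raw[[cn]] <- v
  }
  raw
}

#' Write a BLAST-tabular hit table
#'
#' Inverse of [read_blast_tab()]: headerless, tab-separated.
#'
#' @param hits hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(hits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
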