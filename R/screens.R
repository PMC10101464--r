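#' Thresholds for the annotation screens
#'
#' Taxonomy assignment requires query coverage strictly greater than
#' `tax_qcov` and percent identity strictly greater than `tax_pid`.
#' Virulence-factor hits are retained at identity >= `vf_pid` and subject
#' (VF gene) coverage >= `vf_subject_cov`. Gut-phageome comparison tiers:
#' `match` at qcov >= `gut_qcov` and pid >= `gut_pid`; `full_coverage` at
#' qcov = `gut_full_qcov` and pid >= `gut_full_pid`; `identical` at full
#' coverage and pid = `identical_pid`.
#'
#' @param tax_qcov,tax_pid taxonomy thresholds (strict `>`). Defaults 50, 70.
#' @param vf_pid,vf_subject_cov virulence-factor thresholds (`>=`).
#'   Defaults 90, 90.
#' @param gut_qcov,gut_pid gut match-tier thresholds (`>=`). Defaults 50, 70.
#' @param gut_full_qcov,gut_full_pid full-coverage tier. Defaults 100, 96.
#' @param identical_pid identity required for the identical tier. Default 100.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(tax_qcov = 50, tax_pid = 70,
                          vf_pid = 90, vf_subject_cov = 90,
                          gut_qcov = 50, gut_pid = 70,
                          gut_full_qcov = 100, gut_full_pid = 96,
                          identical_pid = 100) {
  cfg <- list(tax_qcov = tax_qcov, tax_pid = tax_pid, vf_pid = vf_pid,
              vf_subject_cov = vf_subject_cov, gut_qcov = gut_qcov,
              gut_pid = gut_pid, gut_full_qcov = gut_full_qcov,
              gut_full_pid = gut_full_pid, identical_pid = identical_pid)
  if (any(unlist(cfg) < 0 | unlist(cfg) > 100))
    stop("validation error: all thresholds must lie in [0, 100]")
  structure(cfg, class = "screen_config")
}

check_hits <- function(hits, needed) {
  missing <- setdiff(needed, names(hits))
  if (length(missing))
    stop("data error: hit table lacks column(s): ",
         paste(missing, collapse = ", "))
  invisible(hits)
}

#' Assign a taxonomy label from similarity hits
#'
#' Among the hits for one prophage passing both strict thresholds
#' (query coverage > `tax_qcov` and identity > `tax_pid`), the best hit by
#' bitscore is chosen (ties: highest identity, then lexicographically
#' smallest subject id) and its `subject_taxonomy` (or subject id, when no
#' taxonomy column is present) is returned. No qualifying hit gives
#' `"Unknown"`.
#'
#' @param hits hit rows for a single prophage (may be empty).
#' @param cfg a [screen_config()].
#' @return Character scalar taxonomy label.
#' @export
assign_taxonomy <- function(hits, cfg = screen_config()) {
  if (is.null(hits) || nrow(hits) == 0L) return("Unknown")
  check_hits(hits, c("subject_id", "percent_identity", "query_coverage",
                     "bitscore"))
  ok <- hits$query_coverage > cfg$tax_qcov &
    hits$percent_identity > cfg$tax_pid
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return("Unknown")
  ord <- order(-hits$bitscore, -hits$percent_identity, hits$subject_id)
  best <- hits[ord[1], ]
  if ("subject_taxonomy" %in% names(best) && !is.na(best$subject_taxonomy))
    best$subject_taxonomy else best$subject_id
}

#' Assign taxonomy labels for many prophages at once
#'
#' @param hits full hit table (column `query_id` identifies the prophage).
#' @param prophage_ids prophages to label, including ones without hits.
#' @param cfg a [screen_config()].
#' @return Named character vector of labels.
#' @export
assign_taxonomy_all <- function(hits, prophage_ids, cfg = screen_config()) {
  out <- stats::setNames(rep("Unknown", length(prophage_ids)), prophage_ids)
  if (nrow(hits)) {
    for (q in intersect(unique(hits$query_id), prophage_ids))
      out[q] <- assign_taxonomy(hits[hits$query_id == q, , drop = FALSE],
                                cfg)
  }
  out
}

#' Screen hits against a virulence-factor gene set
#'
#' Retains hits with identity >= `vf_pid` and subject (VF gene) coverage >=
#' `vf_subject_cov`, i.e. the aligned query region spans at least that
#' fraction of the virulence gene. Returns one deduplicated VF gene list
#' per prophage.
#'
#' @param hits hit table with `query_id`, `subject_id`, `percent_identity`
#'   and `subject_coverage` columns.
#' @param cfg a [screen_config()].
#' @return Named list: prophage id -> character vector of retained VF genes.
#' @export
vf_screen <- function(hits, cfg = screen_config()) {
  if (nrow(hits) == 0L) return(list())
  check_hits(hits, c("query_id", "subject_id", "percent_identity",
                     "subject_coverage"))
  keep <- hits$percent_identity >= cfg$vf_pid &
    hits$subject_coverage >= cfg$vf_subject_cov
  hits <- hits[keep, , drop = FALSE]
  lapply(split(hits$subject_id, hits$query_id), function(x) sort(unique(x)))
}

#' Tier prophages by similarity to a gut-phageome sequence set
#'
#' Each prophage receives exactly one tier: `identical` if any hit reaches
#' full query coverage at 100% identity; else `full_coverage` if any hit
#' reaches full query coverage at identity >= `gut_full_pid`; else `match`
#' if any hit reaches qcov >= `gut_qcov` and identity >= `gut_pid`; else
#' `none`. The tiers are nested by their defining predicates.
#'
#' @param hits full hit table.
#' @param prophage_ids prophages to tier, including ones without hits.
#' @param cfg a [screen_config()].
#' @return Named factor with levels none < match < full_coverage < identical.
#' @export
gut_compare <- function(hits, prophage_ids, cfg = screen_config()) {
  lv <- c("none", "match", "full_coverage", "identical")
  tier_one <- function(h) {
    if (nrow(h) == 0L) return("none")
    if (any(h$query_coverage >= cfg$gut_full_qcov &
              h$percent_identity >= cfg$identical_pid)) return("identical")
    if (any(h$query_coverage >= cfg$gut_full_qcov &
              h$percent_identity >= cfg$gut_full_pid)) return("full_coverage")
    if (any(h$query_coverage >= cfg$gut_qcov &
              h$percent_identity >= cfg$gut_pid)) return("match")
    "none"
  }
  if (nrow(hits)) check_hits(hits, c("query_id", "percent_identity",
                                     "query_coverage"))
  out <- vapply(prophage_ids, function(q) {
    tier_one(hits[hits$query_id == q, , drop = FALSE])
  }, character(1))
  factor(stats::setNames(out, prophage_ids), levels = lv, ordered = TRUE)
}

#' Flag prophages carrying an integrase gene
#'
#' A prophage is flagged iff any of its gene product descriptions contains
#' "integrase" as a case-insensitive substring.
#'
#' @param gene_table data.frame with `genome_id` (or `prophage_id`) and
#'   `product` columns.
#' @return Named logical vector per prophage.
#' @export
flag_integrase <- function(gene_table) {
  idcol <- if ("prophage_id" %in% names(gene_table)) "prophage_id"
           else "genome_id"
  check_hits(gene_table, c(idcol, "product"))
  hit <- grepl("integrase", gene_table$product, ignore.case = TRUE,
               fixed = FALSE)
  vapply(split(hit, gene_table[[idcol]]), any, logical(1))
}

#' Tabulate antibiotic-resistance genes from caller output
#'
#' Consumes a tabular resistance-gene caller output (one row per hit, with
#' `prophage_id` and `gene_name` columns) and produces per-prophage
#' deduplicated gene lists plus a gene frequency table, where frequency is
#' the number of distinct prophages carrying the gene, sorted descending
#' (ties by gene name).
#'
#' @param calls data.frame with `prophage_id` and `gene_name` columns.
#' @return list with `per_prophage` (named list) and `frequency`
#'   (data.frame: gene_name, n_prophages).
#' @export
arg_tabulate <- function(calls) {
  if (nrow(calls) == 0L)
    return(list(per_prophage = list(),
                frequency = data.frame(gene_name = character(0),
                                       n_prophages = integer(0))))
  check_hits(calls, c("prophage_id", "gene_name"))
  per <- lapply(split(calls$gene_name, calls$prophage_id),
                function(x) sort(unique(x)))
  pairs <- unique(calls[, c("prophage_id", "gene_name")])
  tab <- table(pairs$gene_name)
  freq <- data.frame(gene_name = names(tab), n_prophages = as.integer(tab),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$n_prophages, freq$gene_name), , drop = FALSE]
  rownames(freq) <- NULL
  list(per_prophage = per, frequency = freq)
}

#' Roll taxonomy labels up to morphology family groups
#'
#' Maps free-text taxonomy labels to coarse family groups (myoviruses,
#' podoviruses, siphoviruses, unclassified tailed phages, unclassified
#' bacterial viruses, unknown) via a first-match regex table. The default
#' table covers common caudoviral naming dialects; supply your own mapping
#' to match a different taxonomy dialect.
#'
#' @param labels character vector of taxonomy labels.
#' @param mapping data.frame (pattern, group); patterns are matched
#'   case-insensitively in order, first hit wins.
#' @return Character vector of group names; labels matching nothing map to
#'   "Unclassified bacterial viruses", and "Unknown" stays "Unknown".
#' @export
taxonomy_rollup <- function(labels,
                            mapping = data.frame(
                              pattern = c("myovir", "podovir", "siphovir",
                                          "caudovir"),
                              group = c("Myoviruses", "Podoviruses",
                                        "Siphoviruses",
                                        "Unclassified Caudovirales"),
                              stringsAsFactors = FALSE)) {
  vapply(labels, function(x) {
    if (is.na(x) || identical(x, "Unknown")) return("Unknown")
    for (i in seq_len(nrow(mapping)))
      if (grepl(mapping$pattern[i], x, ignore.case = TRUE))
        return(mapping$group[i])
    "Unclassified bacterial viruses"
  }, character(1), USE.NAMES = !is.null(names(labels)))
}
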