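#' Build a spot-assay matrix from long-format lysis calls
#'
#' @param spots data.frame (phage, strain, replicate, lysis) with lysis in
#'   {0, 1} or logical; every (phage, strain) pair needs >= 1 replicate.
#' @param strains optional metadata data.frame (strain, phylotype, group).
#' @return list of class `spot_matrix` with the long table and metadata.
#' @export
spot_matrix <- function(spots, strains = NULL) {
  needed <- c("phage", "strain", "replicate", "lysis")
  missing <- setdiff(needed, names(spots))
  if (length(missing))
    stop("data error: spots lacks column(s): ",
         paste(missing, collapse = ", "))
  spots$lysis <- as.logical(spots$lysis)
  if (anyNA(spots$lysis)) stop("data error: lysis must be 0/1")
  if (!is.null(strains)) {
    extra <- setdiff(strains$strain, unique(spots$strain))
    if (length(extra))
      stop("data error: metadata for unknown strain(s): ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(spots = spots, strains = strains), class = "spot_matrix")
}

#' Read a spot-assay CSV (long format) and optional strain metadata
#'
#' @param path CSV with columns phage, strain, replicate, lysis.
#' @param strains_path optional CSV with columns strain, phylotype, group.
#' @return A [spot_matrix()].
#' @export
read_spots <- function(path, strains_path = NULL) {
  spots <- utils::read.csv(path, stringsAsFactors = FALSE)
  strains <- if (!is.null(strains_path))
    utils::read.csv(strains_path, stringsAsFactors = FALSE) else NULL
  spot_matrix(spots, strains)
}

#' Collapse technical replicates to one lysis call per (phage, strain)
#'
#' Under the default `"all"` rule a pair is scored as lysed only when every
#' replicate shows complete lysis; under `"any"` one clearing replicate
#' suffices. Single-replicate pairs are identical under both rules.
#'
#' @param x a [spot_matrix()] or long-format data.frame.
#' @param rule `"all"` (default) or `"any"`.
#' @return Logical matrix, phages x strains.
#' @export
aggregate_replicates <- function(x, rule = c("all", "any")) {
  rule <- match.arg(rule)
  spots <- if (inherits(x, "spot_matrix")) x$spots else x
  agg <- stats::aggregate(
    lysis ~ phage + strain, data = spots,
    FUN = if (rule == "all") all else any)
  phages <- sort(unique(spots$phage))
  strains <- sort(unique(spots$strain))
  m <- matrix(FALSE, length(phages), length(strains),
              dimnames = list(phages, strains))
  m[cbind(match(agg$phage, phages), match(agg$strain, strains))] <-
    as.logical(agg$lysis)
  m
}

check_lysis_matrix <- function(lysis, phages = NULL, strains = NULL) {
  stopifnot(is.matrix(lysis), is.logical(lysis))
  if (!is.null(phages)) {
    bad <- setdiff(phages, rownames(lysis))
    if (length(bad)) stop("data error: unknown phage(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(strains)) {
    bad <- setdiff(strains, colnames(lysis))
    if (length(bad)) stop("data error: unknown strain(s): ",
                          paste(bad, collapse = ", "))
  }
  invisible(lysis)
}

#' Number of strains a phage lyses within a strain subset
#'
#' @param lysis aggregated logical matrix from [aggregate_replicates()].
#' @param phage phage id.
#' @param strains strain subset (defaults to all strains).
#' @return Integer count.
#' @export
host_count <- function(lysis, phage, strains = colnames(lysis)) {
  check_lysis_matrix(lysis, phage, strains)
  sum(lysis[phage, strains])
}

#' Pairwise susceptibility table for two phages
#'
#' Counts strains lysed by both phages, by each alone and by neither, over
#' a strain subset; the four categories are mutually exclusive and sum to
#' the subset size.
#'
#' @param lysis aggregated logical matrix.
#' @param phage_a,phage_b phage ids.
#' @param strains strain subset.
#' @return list (phage_a, phage_b, n_both, n_a_only, n_b_only, n_neither,
#'   n_total).
#' @export
pair_table <- function(lysis, phage_a, phage_b,
                       strains = colnames(lysis)) {
  check_lysis_matrix(lysis, c(phage_a, phage_b), strains)
  a <- lysis[phage_a, strains]
  b <- lysis[phage_b, strains]
  list(phage_a = phage_a, phage_b = phage_b,
       n_both = sum(a & b), n_a_only = sum(a & !b),
       n_b_only = sum(!a & b), n_neither = sum(!a & !b),
       n_total = length(strains))
}

#' Coverage of a phage cocktail over a strain subset
#'
#' A strain is covered iff at least one phage in the set lyses it.
#'
#' @param lysis aggregated logical matrix.
#' @param phages non-empty character vector of phage ids.
#' @param strains strain subset.
#' @return list (n_covered, n_total, fraction).
#' @export
cocktail_coverage <- function(lysis, phages, strains = colnames(lysis)) {
  if (!length(phages)) stop("validation error: empty phage set")
  check_lysis_matrix(lysis, phages, strains)
  covered <- apply(lysis[phages, strains, drop = FALSE], 2, any)
  list(n_covered = sum(covered), n_total = length(strains),
       fraction = sum(covered) / length(strains))
}

#' Best phage cocktail of a given size (exhaustive search)
#'
#' Evaluates every size-`k` phage subset and returns the one with maximal
#' coverage; ties are broken lexicographically on the sorted phage ids.
#'
#' @param lysis aggregated logical matrix.
#' @param k cocktail size (<= number of phages).
#' @param strains strain subset.
#' @return list (phages, n_covered, fraction).
#' @export
best_cocktail <- function(lysis, k, strains = colnames(lysis)) {
  phages <- rownames(lysis)
  if (k > length(phages))
    stop("validation error: k exceeds the number of phages")
  combos <- utils::combn(sort(phages), k, simplify = FALSE)
  cov <- vapply(combos, function(set) {
    cocktail_coverage(lysis, set, strains)$n_covered
  }, numeric(1))
  best <- combos[[which.max(cov)]]  # which.max takes the first maximum;
  # combos are generated in lexicographic order, so ties resolve that way
  c(list(phages = best), cocktail_coverage(lysis, best, strains))
}

#' Reconstruct a two-phage lysis matrix from pair-category counts
#'
#' Given the four mutually exclusive category counts of a pairwise
#' susceptibility table (both / a only / b only / neither), builds an
#' explicit per-strain boolean matrix with synthetic strain ids, so that
#' downstream reductions operate on the same representation as raw assay
#' data.
#'
#' @param phage_a,phage_b phage ids.
#' @param n_both,n_a_only,n_b_only,n_neither category counts.
#' @return Logical matrix (2 x total) as from [aggregate_replicates()].
#' @export
lysis_from_pair_counts <- function(phage_a, phage_b, n_both, n_a_only,
                                   n_b_only, n_neither) {
  total <- n_both + n_a_only + n_b_only + n_neither
  a <- c(rep(TRUE, n_both), rep(TRUE, n_a_only),
         rep(FALSE, n_b_only), rep(FALSE, n_neither))
  b <- c(rep(TRUE, n_both), rep(FALSE, n_a_only),
         rep(TRUE, n_b_only), rep(FALSE, n_neither))
  m <- rbind(a, b)
  dimnames(m) <- list(c(phage_a, phage_b),
                      sprintf("strain%03d", seq_len(total)))
  m
}

#' Load the bundled published host-range fixtures
#'
#' `load_table3()` returns the packaged spot-assay matrix of 19 phages
#' against 3 laboratory and 10 urinary E. coli strains (a transcription of
#' a published +/blank lysis table; blank means no complete lysis),
#' aggregated to a logical matrix, together with strain metadata.
#' `load_table4_counts()` returns the packaged pairwise susceptibility
#' category counts for phages T2 and N4 over 103 urinary strains.
#'
#' @return For `load_table3()`: list with `lysis` (logical matrix) and
#'   `strains` (metadata data.frame). For `load_table4_counts()`: named
#'   integer vector (both, n4_only, t2_only, neither).
#' @export
load_table3 <- function() {
  t3 <- utils::read.csv(system.file("extdata", "table3.csv",
                                    package = "prophagenet"),
                        stringsAsFactors = FALSE)
  t3$replicate <- 1L
  meta <- utils::read.csv(system.file("extdata", "strains.csv",
                                      package = "prophagenet"),
                          stringsAsFactors = FALSE)
  sm <- spot_matrix(t3, meta)
  list(lysis = aggregate_replicates(sm), strains = meta)
}

#' @rdname load_table3
#' @export
load_table4_counts <- function() {
  t4 <- utils::read.csv(system.file("extdata", "table4_counts.csv",
                                    package = "prophagenet"),
                        stringsAsFactors = FALSE)
  stats::setNames(as.integer(t4$count), t4$category)
}
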