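#' Percentage with half-away-from-zero rounding and printed string
#'
#' Rounds `100 * numerator / denominator` half away from zero at the
#' requested number of decimals (the convention of most published tables;
#' note base R's `round()` rounds half to even instead) and returns both
#' the raw fraction and the printed string with a `%` suffix.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param decimals digits after the decimal point in the printed string.
#' @return list (fraction, value, string): `fraction` is the unrounded
#'   proportion in `[0, 1]`, `value` the rounded percentage.
#' @examples
#' percent(1807, 3038, 2)$string  # "59.48%"
#' @export
percent <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("validation error: denominator must be > 0")
  frac <- numerator / denominator
  p <- 100 * frac
  f <- 10^decimals
  val <- sign(p) * floor(abs(p) * f + 0.5) / f
  list(fraction = frac, value = val,
       string = sprintf(paste0("%.", decimals, "f%%"), val))
}

#' Summarize a prophage catalog
#'
#' Tallies a prophage catalog into the headline counts of such analyses:
#' prophages per completeness class, genomes with at least one intact
#' prophage, integrase/VF/ARG carriage, sequence-cluster statistics and
#' gut-phageome tier counts. Consistency is enforced: completeness class
#' counts must sum to the total and every prophage must map to a known
#' genome.
#'
#' @param prophages data.frame (prophage_id, genome_id, completeness) with
#'   completeness in {"intact", "questionable", "incomplete"}.
#' @param genome_ids character vector of all genomes screened.
#' @param integrase named logical vector per intact prophage (optional).
#' @param vf_genes,arg_genes named lists per prophage (optional).
#' @param clusters output of [greedy_cluster()] (optional).
#' @param gut_tiers factor from [gut_compare()] (optional).
#' @return list of class `catalog_summary`; percentages are reported both
#'   as fractions and printed strings (see [percent()]).
#' @export
catalog_summary <- function(prophages, genome_ids, integrase = NULL,
                            vf_genes = NULL, arg_genes = NULL,
                            clusters = NULL, gut_tiers = NULL) {
  bad <- setdiff(prophages$genome_id, genome_ids)
  if (length(bad))
    stop("integrity error: prophage(s) reference unknown genome(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  classes <- c("intact", "questionable", "incomplete")
  if (!all(prophages$completeness %in% classes))
    stop("integrity error: unknown completeness class(es): ",
         paste(setdiff(unique(prophages$completeness), classes),
               collapse = ", "))
  n_class <- vapply(classes, function(cl) {
    sum(prophages$completeness == cl)
  }, integer(1))
  stopifnot(sum(n_class) == nrow(prophages))  # conservation, by construction
  intact <- prophages[prophages$completeness == "intact", , drop = FALSE]
  with_intact <- unique(intact$genome_id)
  out <- list(
    n_genomes = length(genome_ids),
    n_prophages = nrow(prophages),
    n_by_class = n_class,
    n_genomes_with_intact = length(with_intact),
    pct_genomes_with_intact = if (length(genome_ids))
      percent(length(with_intact), length(genome_ids), 0) else NULL)
  n_intact <- nrow(intact)
  if (!is.null(integrase) && n_intact > 0) {
    n_int <- sum(integrase[intact$prophage_id], na.rm = TRUE)
    out$n_with_integrase <- n_int
    out$pct_with_integrase <- percent(n_int, n_intact, 2)
  }
  if (!is.null(vf_genes) && n_intact > 0) {
    n_vf <- sum(intact$prophage_id %in% names(vf_genes)[
      lengths(vf_genes) > 0])
    out$n_with_vf <- n_vf
    out$pct_with_vf <- percent(n_vf, n_intact, 0)
  }
  if (!is.null(arg_genes) && n_intact > 0) {
    n_arg <- sum(intact$prophage_id %in% names(arg_genes)[
      lengths(arg_genes) > 0])
    out$n_with_arg <- n_arg
    out$pct_with_arg <- percent(n_arg, n_intact, 2)
  }
  if (!is.null(clusters)) {
    cs <- cluster_summary(clusters)
    out$clusters <- cs
    out$pct_singletons <- percent(cs$n_singletons, cs$n_clusters, 2)
  }
  if (!is.null(gut_tiers)) {
    out$gut_tier_counts <- table(gut_tiers)
  }
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Prophage catalog summary\n")
  cat(sprintf("  genomes screened:            %d\n", x$n_genomes))
  cat(sprintf("  prophages:                   %d (intact %d, questionable %d, incomplete %d)\n",
              x$n_prophages, x$n_by_class[["intact"]],
              x$n_by_class[["questionable"]], x$n_by_class[["incomplete"]]))
  if (!is.null(x$pct_genomes_with_intact))
    cat(sprintf("  genomes with intact phage:   %d (%s)\n",
                x$n_genomes_with_intact, x$pct_genomes_with_intact$string))
  if (!is.null(x$n_with_integrase))
    cat(sprintf("  intact with integrase:       %d (%s)\n",
                x$n_with_integrase, x$pct_with_integrase$string))
  if (!is.null(x$n_with_vf))
    cat(sprintf("  intact with virulence genes: %d (%s)\n",
                x$n_with_vf, x$pct_with_vf$string))
  if (!is.null(x$n_with_arg))
    cat(sprintf("  intact with resistance genes:%d (%s)\n",
                x$n_with_arg, x$pct_with_arg$string))
  if (!is.null(x$clusters))
    cat(sprintf("  sequence clusters:           %d (%d singletons, %s; largest %d)\n",
                x$clusters$n_clusters, x$clusters$n_singletons,
                x$pct_singletons$string, x$clusters$largest_size))
  invisible(x)
}
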