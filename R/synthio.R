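#' Simulation configuration for synthetic prophage catalogs
#'
#' Defines the planted-family structure used by the synthetic prophage
#' generator. Each of `n_families` phage families owns a disjoint pool of
#' `modules_per_family` gene modules with `genes_per_module` genes each.
#' Module 1 of every family is the core module (present in every genome of
#' the family); the remaining modules are accessory and are dropped
#' independently per genome with probability `mosaicism_rate`, emulating
#' the mosaic gene content of real prophages. Every gene copy is the family
#' ancestor mutated i.i.d. per site at `mutation_rate`.
#'
#' @param n_families number of planted phage families.
#' @param modules_per_family gene modules per family (module 1 is core).
#' @param genes_per_module genes per module.
#' @param genomes_per_family genomes simulated per family.
#' @param mosaicism_rate per-genome probability that an accessory module is
#'   absent, in `[0, 1]`.
#' @param mutation_rate per-site substitution probability, in `[0, 1]`.
#' @param gene_length length of every ancestral gene, in bp.
#' @param seed integer seed; identical configurations produce byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_families = 2, genomes_per_family = 3, seed = 1)
#' sim <- simulate_prophages(cfg)
#' nrow(sim$truth$genomes)
#' @export
sim_config <- function(n_families = 3, modules_per_family = 2,
                       genes_per_module = 3, genomes_per_family = 5,
                       mosaicism_rate = 0.25, mutation_rate = 0.03,
                       gene_length = 500, seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    modules_per_family = as.integer(modules_per_family),
    genes_per_module = as.integer(genes_per_module),
    genomes_per_family = as.integer(genomes_per_family),
    mosaicism_rate = as.numeric(mosaicism_rate),
    mutation_rate = as.numeric(mutation_rate),
    gene_length = as.integer(gene_length),
    seed = as.integer(seed)
  )
  counts <- c("n_families", "modules_per_family", "genes_per_module",
              "genomes_per_family", "gene_length")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("configuration error: '", f, "' must be a count >= 1")
  }
  for (f in c("mosaicism_rate", "mutation_rate")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: '", f, "' must be a probability in [0, 1]")
  }
  if (is.na(cfg$seed)) stop("configuration error: 'seed' must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

# Run `code` under a deterministic RNG state without touching the caller's
# .Random.seed (reproducibility contract: no global RNG state leaks).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Generate ancestral gene sequences for the planted families
#'
#' Draws one ancestral nucleotide sequence per gene, uniform over A/C/G/T,
#' from the seeded stream. Gene ids encode family, module and gene index
#' (`F<f>_M<m>_G<g>`); module 1 is the family's core module.
#'
#' @param cfg a [sim_config()].
#' @return Named character vector of ancestor sequences.
#' @export
gen_gene_families <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- character(0)
  for (f in seq_len(cfg$n_families))
    for (m in seq_len(cfg$modules_per_family))
      for (g in seq_len(cfg$genes_per_module))
        ids <- c(ids, sprintf("F%d_M%d_G%d", f, m, g))
  seqs <- with_seed(cfg$seed, random_dna(length(ids), cfg$gene_length))
  names(seqs) <- ids
  seqs
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    alphabet <- c("A", "C", "G", "T")
    for (i in hit) {
      # substitute with a different base, uniformly
      bases[i] <- sample(setdiff(alphabet, bases[i]), 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Simulate prophage genomes from planted gene families
#'
#' Each genome carries all genes of its family's core module, plus each
#' accessory module independently with probability `1 - mosaicism_rate`.
#' Every gene copy is the ancestor mutated i.i.d. per site at
#' `mutation_rate`; the genome sequence is the concatenation of its genes in
#' module order. Coordinates in the gene table are 0-based half-open and all
#' genes are emitted on the + strand. The first core gene of every genome is
#' annotated as a site-specific integrase so that annotation screens have a
#' positive signal; all other genes are hypothetical proteins.
#'
#' @param cfg a [sim_config()].
#' @param ancestors output of [gen_gene_families()]; generated from `cfg`
#'   when omitted.
#' @return A list with elements `genomes` (named character vector of genome
#'   sequences), `genes` (named character vector of gene copies),
#'   `gene_table` (data.frame: gene_id, genome_id, start, end, strand,
#'   product) and `truth` (list of data.frames `genomes` and `genes` giving
#'   the planted family/module labels).
#' @export
gen_prophage_genomes <- function(cfg, ancestors = gen_gene_families(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  anc_mod <- sub("^F\\d+_M(\\d+)_G\\d+$", "\\1", names(ancestors))
  anc_fam <- sub("^F(\\d+)_.*$", "\\1", names(ancestors))

  genome_ids <- character(0)
  genome_fams <- integer(0)
  genome_seqs <- character(0)
  gene_seqs <- character(0)
  gt <- list()
  truth_genes <- list()

  with_seed(cfg$seed + 1L, {
    for (f in seq_len(cfg$n_families)) {
      for (g in seq_len(cfg$genomes_per_family)) {
        gid <- sprintf("F%d_g%d", f, g)
        keep_mod <- c(TRUE, stats::runif(cfg$modules_per_family - 1L) >=
                        cfg$mosaicism_rate)
        sel <- which(anc_fam == as.character(f) &
                       keep_mod[as.integer(anc_mod)])
        pos <- 0L
        parts <- character(length(sel))
        for (k in seq_along(sel)) {
          a <- sel[k]
          copy <- mutate_seq(ancestors[[a]], cfg$mutation_rate)
          copy_id <- paste0(gid, "|", names(ancestors)[a])
          len <- nchar(copy)
          product <- if (k == 1L) "site-specific integrase"
                     else "hypothetical protein"
          gt[[length(gt) + 1L]] <- data.frame(
            gene_id = copy_id, genome_id = gid,
            start = pos, end = pos + len, strand = "+",
            product = product, stringsAsFactors = FALSE)
          truth_genes[[length(truth_genes) + 1L]] <- data.frame(
            gene_id = copy_id, genome_id = gid,
            module = sprintf("F%d_M%s", f, anc_mod[a]),
            family = sprintf("F%d", f), stringsAsFactors = FALSE)
          gene_seqs[copy_id] <- copy
          parts[k] <- copy
          pos <- pos + len
        }
        genome_ids <- c(genome_ids, gid)
        genome_fams <- c(genome_fams, f)
        genome_seqs <- c(genome_seqs, paste(parts, collapse = ""))
      }
    }
  })

  names(genome_seqs) <- genome_ids
  list(
    genomes = genome_seqs,
    genes = gene_seqs,
    gene_table = do.call(rbind, gt),
    truth = list(
      genomes = data.frame(genome_id = genome_ids,
                           family = sprintf("F%d", genome_fams),
                           stringsAsFactors = FALSE),
      genes = do.call(rbind, truth_genes)
    )
  )
}

#' Simulate a full synthetic prophage catalog
#'
#' Convenience wrapper chaining [gen_gene_families()] and
#' [gen_prophage_genomes()].
#'
#' @param cfg a [sim_config()].
#' @return See [gen_prophage_genomes()]; the ancestors are attached as
#'   element `ancestors`.
#' @export
simulate_prophages <- function(cfg) {
  anc <- gen_gene_families(cfg)
  out <- gen_prophage_genomes(cfg, anc)
  out$ancestors <- anc
  out
}

#' Build a similarity hit table with requested coverage and identity
#'
#' Emits rows following the BLAST tabular (outfmt 6) column convention with
#' query-coverage (`qcovs`) and subject-coverage (`scovs`) columns appended,
#' so that annotation screens can be exercised with controlled inputs.
#' Alignment statistics are back-filled deterministically from the requested
#' coverage/identity (alignment length from `qcov` and `qlen`, mismatches
#' from `pident`).
#'
#' @param spec data.frame with columns `query`, `subject`, `qcov`, `pid`
#'   and optionally `scov` (defaults to `qcov`) and `taxonomy`.
#' @param qlen nominal query length in bp used to back-fill coordinates.
#' @return data.frame of hit rows as read by [read_blast_tab()], plus a
#'   `subject_taxonomy` column when `taxonomy` was supplied.
#' @export
gen_hit_table <- function(spec, qlen = 1000L) {
  cols <- c("query", "subject", "qcov", "pid")
  if (!is.data.frame(spec)) stop("validation error: 'spec' must be a data.frame")
  if (nrow(spec) == 0L) return(empty_hit_table())
  if (!all(cols %in% names(spec)))
    stop("validation error: spec needs columns ", paste(cols, collapse = ", "))
  if (any(spec$qcov < 0 | spec$qcov > 100 | spec$pid < 0 | spec$pid > 100))
    stop("validation error: qcov and pid must lie in [0, 100]")
  scov <- if ("scov" %in% names(spec)) spec$scov else spec$qcov
  if (any(scov < 0 | scov > 100))
    stop("validation error: scov must lie in [0, 100]")
  len <- pmax(1L, as.integer(round(spec$qcov / 100 * qlen)))
  mism <- as.integer(round((1 - spec$pid / 100) * len))
  out <- data.frame(
    query_id = as.character(spec$query),
    subject_id = as.character(spec$subject),
    percent_identity = as.numeric(spec$pid),
    alignment_length = len,
    mismatches = mism,
    gap_openings = 0L,
    q_start = 1L, q_end = len,
    s_start = 1L, s_end = len,
    evalue = 0, bitscore = round(2 * len * spec$pid / 100, 1),
    query_coverage = as.numeric(spec$qcov),
    subject_coverage = as.numeric(scov),
    stringsAsFactors = FALSE)
  if ("taxonomy" %in% names(spec))
    out$subject_taxonomy <- as.character(spec$taxonomy)
  out
}

#' An empty hit table with the standard screen columns
#'
#' @return Zero-row data.frame with the columns produced by
#'   [gen_hit_table()] and [read_blast_tab()].
#' @export
empty_hit_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatches = integer(0), gap_openings = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             query_coverage = numeric(0), subject_coverage = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a spot-assay lysis matrix
#'
#' Draws one lysis propensity per (phage, strain) pair: with probability
#' `breadth` the phage lyses the strain. When `noise` is positive each
#' technical replicate independently flips the underlying call with that
#' probability; with `noise = 0` replicates agree exactly.
#'
#' @param n_phages,n_strains matrix dimensions.
#' @param breadth per-(phage,strain) probability of lysis.
#' @param replicates technical replicates per pair (>= 1).
#' @param seed integer seed.
#' @param noise per-replicate flip probability.
#' @return Long-format data.frame (phage, strain, replicate, lysis) as
#'   consumed by [spot_matrix()].
#' @export
gen_spot_matrix <- function(n_phages, n_strains, breadth, replicates = 4L,
                            seed = 1L, noise = 0) {
  if (replicates < 1L) stop("validation error: replicates must be >= 1")
  if (breadth < 0 || breadth > 1)
    stop("validation error: breadth must be a probability")
  phages <- sprintf("phage%02d", seq_len(n_phages))
  strains <- sprintf("strain%02d", seq_len(n_strains))
  with_seed(seed, {
    base <- matrix(stats::runif(n_phages * n_strains) < breadth,
                   n_phages, n_strains)
    rows <- expand.grid(replicate = seq_len(replicates),
                        strain = strains, phage = phages,
                        stringsAsFactors = FALSE)[, c(3, 2, 1)]
    lysis <- base[cbind(match(rows$phage, phages),
                        match(rows$strain, strains))]
    if (noise > 0) {
      flip <- stats::runif(nrow(rows)) < noise
      lysis <- xor(lysis, flip)
    }
    rows$lysis <- as.integer(lysis)
    rows
  })
}

#' Write a simulated catalog to disk
#'
#' Emits `genomes.fasta`, `genes.fasta` (70-column wrapped), `genes.tsv`,
#' `truth_genomes.tsv` and `truth_genes.tsv` under `dir`.
#'
#' @param sim output of [simulate_prophages()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genomes, file.path(dir, "genomes.fasta"))
  write_fasta(sim$genes, file.path(dir, "genes.fasta"))
  write_tsv(sim$gene_table, file.path(dir, "genes.tsv"))
  write_tsv(sim$truth$genomes, file.path(dir, "truth_genomes.tsv"))
  write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
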