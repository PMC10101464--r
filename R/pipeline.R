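#' Run the full prophage catalog pipeline on a simulated dataset
#'
#' Chains every stage end to end: simulate a catalog with planted families,
#' cluster genes into homolog families (minbit + MCL), build the
#' gene-sharing network and its connected components, cluster the genome
#' sequences at the species level and summarize. All randomness derives
#' from `cfg$seed`, so one configuration yields bit-identical artifacts.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, all stage artifacts
#'   (FASTA/TSV/clstr/SIF files) are written beneath it.
#' @param minbit minbit cutoff for the gene-family stage.
#' @param mcl an [mcl_params()].
#' @param clustering a [cluster_config()].
#' @param minw edge-weight threshold for the network stage.
#' @return list with `sim`, `gene_clusters`, `presence`, `network`,
#'   `clusters` and `summary`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, minbit = 0.35,
                         mcl = mcl_params(), clustering = cluster_config(),
                         minw = 0) {
  sim <- simulate_prophages(cfg)
  pan <- cluster_genes(sim$genes, minbit = minbit, params = mcl)
  P <- build_presence_matrix(pan$assignments, sim$gene_table)
  net <- build_network(P, minw = minw)
  seq_clusters <- greedy_cluster(sim$genomes, clustering)
  prophages <- data.frame(prophage_id = names(sim$genomes),
                          genome_id = names(sim$genomes),
                          completeness = "intact",
                          stringsAsFactors = FALSE)
  gt <- sim$gene_table
  names(gt)[names(gt) == "genome_id"] <- "prophage_id"
  summary <- catalog_summary(prophages, names(sim$genomes),
                             integrase = flag_integrase(gt),
                             clusters = seq_clusters)
  if (!is.null(out_dir)) {
    write_sim(sim, file.path(out_dir, "sim"))
    write_tsv(pan$assignments, file.path(out_dir, "gene_clusters.tsv"))
    write_tsv(pan$edges, file.path(out_dir, "gene_edges.tsv"))
    export_network(net, file.path(out_dir, "network"))
    write_clstr(seq_clusters, file.path(out_dir, "clusters.clstr"))
    write_representatives(seq_clusters, sim$genomes,
                          file.path(out_dir, "representatives.fasta"))
  }
  list(sim = sim, gene_clusters = pan, presence = P, network = net,
       clusters = seq_clusters, summary = summary)
}
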