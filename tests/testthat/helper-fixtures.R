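# Shared expensive fixtures, computed once per test run.

# Three planted families, five genomes each, no mosaicism (so that all
# genomes of a family carry the full module complement and species-level
# clustering is well-posed), 3% per-site mutation.
e2e_config <- function() {
  sim_config(n_families = 3, modules_per_family = 2, genes_per_module = 3,
             genomes_per_family = 5, mosaicism_rate = 0,
             mutation_rate = 0.03, gene_length = 500, seed = 101L)
}

pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(e2e_config())
    cache
  }
})

# Small mosaic simulation for network/matrix tests.
mosaic_sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_prophages(
        sim_config(n_families = 3, modules_per_family = 3,
                   genes_per_module = 2, genomes_per_family = 4,
                   mosaicism_rate = 0.3, mutation_rate = 0.02,
                   gene_length = 200, seed = 7L))
    cache
  }
})
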