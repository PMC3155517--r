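# Small simulation configuration for fast unit tests; the acceptance
# tests use the full default configuration.

small_sim_config <- function(seed = 101L, ...) {
  base <- list(
    seed = seed, n_chrom = 2L, chrom_length = 15000L,
    n_genes = 10L, n_repeat_loci = 6L, n_mirna_loci = 4L,
    n_antisense_loci = 4L, n_rrna = 2L, n_trna = 2L,
    n_target_sites = 4L, depth_mirna = 4, depth_rasirna = 3,
    depth_antisense = 3, depth_star = 2
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# one shared small end-to-end dataset, built once per test run
small_sim_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_sim_config()
      gen <- generate_genome(cfg)
      reads <- simulate_reads(gen$bundle, gen$truth, cfg)
      cache <<- list(cfg = cfg, gen = gen, reads = reads)
    }
    cache
  }
})
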