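# One shared default-world simulation plus its pipeline run, built lazily
# and cached for the whole test session (several files score against it).

.sim_cache <- new.env(parent = emptyenv())

# default-geometry world at the acceptance scale: >= 200 planted IPACs
acceptance_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- simulation_config(n_genes = 200L, n_sites = 300L, seed = 20260910L)
    .sim_cache$sim <- simulate_dataset(cfg)
  }
  .sim_cache$sim
}

# the pipeline run on that world, with the published fixed 700-nt SE cutoff
# (the planted SE geometry is defined by it)
acceptance_run <- function() {
  if (is.null(.sim_cache$run)) {
    sim <- acceptance_sim()
    cfg <- pipeline_config(gff3 = sim$gff3, fasta = sim$fasta,
                           tags = sim$tags_bed, seed = 20260910L,
                           se_cutoff_nt = 700L)
    .sim_cache$run <- run_pipeline(cfg)
  }
  .sim_cache$run
}

# planted sites joined to the pipeline's classified records by dominant site
acceptance_joined <- function() {
  sim <- acceptance_sim()
  run <- acceptance_run()
  merge(sim$truth, run$records,
        by.x = c("chrom", "pos", "strand"),
        by.y = c("chrom", "dominant_site", "strand"))
}
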