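# Shared small simulated clade, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(
      species_tree = "((gA:0.02,gB:0.02):0.02,(gC:0.03,gD:0.01):0.02);",
      chromosomes = 2L, genes_per_chromosome = 30L, family_seed_count = 4L,
      rng_seed = 7L)
    .fixture_env$sim <- simulate_clade(cfg)
  }
  .fixture_env$sim
}

small_identify <- function() {
  if (is.null(.fixture_env$idf)) {
    sim <- small_sim()
    .fixture_env$idf <- identify_family(sim$genomes, sim$seed_msas)
  }
  .fixture_env$idf
}
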