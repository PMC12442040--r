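# Shared simulations, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

# small phantom for unit tests
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- suppressWarnings(
      simulate_msi(phantom_spec(24, 24, seed = 42))
    )
  }
  .sim_cache$small
}

# the default study-scale phantom used by the acceptance-style checks
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- suppressWarnings(
      simulate_msi(phantom_spec(64, 64, seed = 20250929 %% 1000L))
    )
  }
  .sim_cache$default
}

default_pipeline <- function() {
  if (is.null(.sim_cache$pipeline)) {
    sim <- default_sim()
    .sim_cache$pipeline <- run_kmd_pipeline(sim$dataset,
                                            matrix_mz = sim$matrix_ions$mz)
  }
  .sim_cache$pipeline
}

# map each planted species to the canonical point whose collapsed group
# contains at least one consensus bin matching one of that species' planted
# ion m/z values
species_canonical_map <- function(sim, pipeline, tol_ppm = 3) {
  ions <- sim$ions
  filtered <- pipeline$filtered
  out <- lapply(split(ions, ions$species), function(si) {
    hits <- unique(unlist(lapply(si$mz, function(m) {
      filtered$group_id[abs(ppm_error(filtered$mz, m)) <= tol_ppm]
    })))
    hits[!is.na(hits)]
  })
  out
}
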