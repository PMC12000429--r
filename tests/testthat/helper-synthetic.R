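# Shared, memoised synthetic runs so that expensive 120-cycle pipelines are
# computed once per suite. Seeds are fixed; everything is generated in code.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(mode, noisy, n_cycles = 120, seed = 1) {
  key <- paste(mode, noisy, n_cycles, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    nm <- if (noisy) noise_model(seed = NULL) else noise_model_none()
    .sim_cache[[key]] <- simulate_gait(mode, n_cycles = n_cycles, seed = seed,
                                       noise = nm)
  }
  .sim_cache[[key]]
}

cached_analysis <- function(mode, noisy, n_cycles = 120, seed = 1) {
  key <- paste("an", mode, noisy, n_cycles, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    sim <- cached_sim(mode, noisy, n_cycles, seed)
    .sim_cache[[key]] <- analyze_gait(sim$log, n_keep = n_cycles)
  }
  .sim_cache[[key]]
}

# small percent-GC grid used by detector unit tests
make_pct_grid <- function(n = 1000) seq(0, 100, length.out = n + 1)[1:n]
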