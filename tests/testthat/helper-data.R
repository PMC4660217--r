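# shared fixtures, built once per test run

# the default-condition simulated dataset used across modules
default_sim <- simulate_dataset(sim_config())

# scaled pipeline settings used wherever the full pipeline is exercised
scaled_config <- function(seed = 1, ...) {
  mmra_config(n_boot_ks = 1000, n_iter_enrich = 100, n_null_mi = 20000,
              n_boot_regulon = 50, consensus_p = 1e-6, sd_min = 0.7,
              seed = seed, ...)
}

# a small paired dataset for cheap structural tests
tiny_sim <- simulate_dataset(sim_config(
  n_per_subtype = 20, n_genes = 120, n_mirnas = 12, n_targets = 10,
  n_decoy_targets = 5, n_shifted_up = 5, n_stale = 10, seed = 11))

# exact upper-tail hypergeometric by direct enumeration of the tail
enum_hyper_upper <- function(k, S, U, Tn) {
  kk <- k:min(S, Tn)
  sum(choose(S, kk) * choose(U - S, Tn - kk)) / choose(U, Tn)
}
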