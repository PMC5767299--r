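# Shared, lazily computed simulation results. The dispersal validation runs
# feed several test files (dispersal statistics, trapping, acceptance), so
# they are computed once per test session and reused.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

dispersal_runs <- function(temperature, extrinsic_risk = 0.02) {
  key <- sprintf("disp_%s_%s", temperature, extrinsic_risk)
  cached(key, validation_dispersal_experiment(
    temperature, extrinsic_risk = extrinsic_risk,
    n_replicates = 5L, master_seed = 1L))
}

invasion_runs <- function(site, climate = "med", n = 15L, ...) {
  key <- sprintf("inv_%s_%s_%d", site, climate, n)
  cached(key, invasion_experiment(site, climate, n = n, master_seed = 1L, ...))
}

# Exact binomial 95% confidence band around a reference proportion observed
# as x successes out of n replicates (the reference experiments used 15).
binom_band <- function(p_ref, n_ref = 15L) {
  x <- round(p_ref * n_ref)
  as.numeric(stats::binom.test(x, n_ref)$conf.int)
}
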