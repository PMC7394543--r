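# Shared fixtures built in code; all randomness goes through explicit seeds.

# A small cohort reused by several files (cheap to build once).
small_cohort <- function(seed = 101, n_lipids = 2, ...) {
  simulate_twin_cohort(twin_sim_config(
    n_mz_pairs = 40, n_dz_pairs = 30, n_lipids = n_lipids, seed = seed, ...))
}

# Large single-lipid cohort for asymptotic checks (built once per run).
big_pairs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_twin_cohort(twin_sim_config(
        n_mz_pairs = 5000, n_dz_pairs = 5000, n_lipids = 1,
        a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 424))
      cache <<- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
    }
    cache
  }
})

# Hand-enumerated survivor set of the default raw-peak fixture.
expected_qc_survivors <- c("Cer(d18:1/16:0)", "PC(16:0/18:1)",
                           "TG(16:0/18:1/18:2)", "PI(18:0/20:4)")
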