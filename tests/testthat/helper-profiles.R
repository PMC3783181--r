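# construct a speed_profile directly from smoothed values, for unit tests
# of threshold/feature/sensitivity logic that do not need a rate engine
fake_profile <- function(smoothed, gene = "g", condition = "c1",
                         window = 1L) {
  structure(list(gene_id = gene, condition = condition,
                 raw_times = smoothed, smoothed_times = smoothed,
                 speed = 1 / smoothed, window = as.integer(window),
                 usable = TRUE),
            class = "speed_profile")
}

# standard toy fixture: calibrated pool + gene set under one seed
toy_fixture <- function(seed = 42L,
                        perturbation = list(mode = "uniform",
                                            factors = c(c2 = 0.5))) {
  spec <- fixture_spec(seed, perturbation = perturbation)
  pool <- make_pool(spec)
  list(spec = spec, pool = pool, genes = make_cds_set(spec),
       conditions = perturb_pool(pool, spec))
}
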