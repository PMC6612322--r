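# Scaled-down tumour conditions used by the multicellular tests: a 60 um
# domain at the same EGF concentration as the 120 um default (the cell-free
# stationary count scales with domain volume), 2 simulated days.
tumour_test_config <- function(...) {
  base <- list(domain_radius = 60, shell_thickness = 5,
               introduction_rate = 22 / 8)
  do.call(sim_config, modifyList(base, list(...)))
}

# time-averaged population over the 2-day horizon: integrates the growth
# curve, which is a lower-variance summary than the endpoint count
tumour_growth_levels <- function(n_egfr, profile, reps, seed0) {
  cfg <- tumour_test_config(n_egfr = as.integer(n_egfr))
  vapply(seq_len(reps), function(r) {
    res <- run_tumour(cfg, profile = profile, horizon_min = 2880,
                      seed = seed0 + 101 * r +
                        n_egfr * (profile == "normal"),
                      record_every_min = 120)
    mean(res$population$n_cells)
  }, numeric(1))
}
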