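test_that("an empty world only advances the clock", {
  cfg <- sim_config(introduction_rate = 0)
  st <- new_simulation(cfg, seed = 61, n_cells = 0)
  out <- sim_step(st, 100)
  expect_equal(out$clock, 100 * cfg$dt)
  expect_length(out$cells, 0)
  expect_equal(nrow(out$field$pos), 0)
})

test_that("runs are bit-reproducible under a fixed seed", {
  st1 <- make_fixture("mini-tumour", seed = 8)
  st2 <- make_fixture("mini-tumour", seed = 8)
  a <- sim_step(st1, 400, record_every = 100)
  b <- sim_step(st2, 400, record_every = 100)
  expect_identical(attr(a, "records"), attr(b, "records"))
  expect_equal(unclass(a)[c("clock", "field", "cells")],
               unclass(b)[c("clock", "field", "cells")])

  r1 <- run_single_cell("normal", replicates = 2L, t_end = 5, seed = 3)
  r2 <- run_single_cell("normal", replicates = 2L, t_end = 5, seed = 3)
  expect_identical(r1, r2)
})

test_that("binned and brute-force overlap searches give identical dynamics", {
  for (seed in c(5, 17)) {
    cfg_g <- sim_config(use_grid = TRUE, field_enabled = FALSE,
                        mechanics_enabled = FALSE, fate_enabled = FALSE)
    cfg_b <- sim_config(use_grid = FALSE, field_enabled = FALSE,
                        mechanics_enabled = FALSE, fate_enabled = FALSE)
    mk <- function(cfg) {
      st <- new_simulation(cfg, seed = seed, n_cells = 1)
      st$cells[[1]]$receptors <- list(anchor = matrix(c(0, 0, 1), ncol = 3),
                                      state = 1L, soff = 1e9)
      st
    }
    a <- sim_step(mk(cfg_g), 2000, record_every = 200)
    b <- sim_step(mk(cfg_b), 2000, record_every = 200)
    expect_identical(attr(a, "records"), attr(b, "records"))
    expect_equal(a$cells[[1]]$interior, b$cells[[1]]$interior)
  }
})

test_that("the operator order flag permutes the split without breaking it", {
  st1 <- make_fixture("mini-tumour", seed = 12)
  st1$config <- sim_config(modifyList(unclass(st1$config),
                                      list(operator_order = "imf")))
  out <- sim_step(st1, 50)
  expect_s3_class(out, "egfr_state")
  expect_gt(out$clock, 0)
})

test_that("ensemble helpers summarize runs and locate peaks", {
  runs <- data.frame(replicate = rep(1:2, each = 3),
                     time = rep(c(0, 1, 2), 2),
                     ras = c(0, 2, 4, 0, 4, 8), raf = 0, erk = 0,
                     tf = c(0, 10, 2, 0, 12, 2))
  em <- ensemble_mean(runs)
  expect_equal(em$ras, c(0, 3, 6))
  expect_equal(em$tf, c(0, 11, 2))
  expect_equal(peak_time(em$time, em$tf, window = 1), 1)

  # smoothing: a lone spike does not beat a sustained plateau
  t <- 0:100
  v <- c(rep(0, 20), rep(10, 30), rep(0, 51))
  v[90] <- 12
  expect_lt(peak_time(t, v, window = 11), 60)
})

test_that("convergence summaries pick the largest statistically stable step", {
  conv <- data.frame(
    dt = rep(c(0.02, 0.01, 0.005), each = 3),
    species = rep(c("ras", "raf", "erk"), 3),
    mean = c(30, 20, 10, 21, 14, 7, 20, 13, 7.2),
    se = rep(1, 9))
  expect_equal(converged_dt(conv, z_crit = 3), 0.01)
  conv$mean[1:3] <- c(20.5, 13.5, 7.1)
  expect_equal(converged_dt(conv, z_crit = 3), 0.02)
})
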