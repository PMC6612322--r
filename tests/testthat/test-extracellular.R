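small_cfg <- function(...) {
  base <- list(domain_radius = 30, shell_thickness = 3, introduction_rate = 2,
               degradation_rate = 0.1, dt = 0.02)
  do.call(sim_config, modifyList(base, list(...)))
}

test_that("EGF introduction is Poisson on the outer shell", {
  cfg <- small_cfg()
  s <- rng_stream(21)
  f <- new_field(cfg)

  # zero rate adds nothing
  f0 <- introduce_egf(f, dt = 1, clock = 0, s, sim_config(introduction_rate = 0))
  expect_equal(nrow(f0$pos), 0)

  # mean additions ~ rate * dt, all inside the shell, degradation in future
  added <- numeric(200)
  for (k in 1:200) {
    fk <- introduce_egf(f, dt = 1, clock = 5, s, cfg)
    added[k] <- nrow(fk$pos)
    if (added[k] > 0) {
      r <- sqrt(rowSums(fk$pos^2))
      expect_true(all(r >= cfg$domain_radius - cfg$shell_thickness - 1e-9 &
                        r <= cfg$domain_radius + 1e-9))
      expect_true(all(fk$deg_time > 5))
    }
  }
  expect_equal(mean(added), cfg$introduction_rate * 1, tolerance = 0.15)
})

test_that("a cell-free field relaxes to the birth-death stationary mean", {
  cfg <- small_cfg(mechanics_enabled = FALSE, fate_enabled = FALSE)
  st <- new_simulation(cfg, seed = 31, n_cells = 0)
  # 10 mean lifetimes of warmup, then time-average
  st <- sim_step(st, round(100 / cfg$dt))
  st <- sim_step(st, round(300 / cfg$dt), record_every = 25L)
  counts <- attr(st, "records")$n_egf
  target <- cfg$introduction_rate / cfg$degradation_rate
  expect_equal(mean(counts), target, tolerance = 0.10)

  # near-instant degradation empties the field (up to the handful of
  # particles introduced during the very last step)
  cfg2 <- small_cfg(degradation_rate = 1e6, mechanics_enabled = FALSE,
                    fate_enabled = FALSE)
  st2 <- new_simulation(cfg2, seed = 32, n_cells = 0)
  st2 <- sim_step(st2, 100)
  expect_lte(nrow(st2$field$pos), 3)
  # and with introduction switched off it is exactly empty
  cfg3 <- small_cfg(introduction_rate = 0, degradation_rate = 1e6,
                    mechanics_enabled = FALSE, fate_enabled = FALSE)
  st3 <- new_simulation(cfg3, seed = 32, n_cells = 0)
  st3$field <- list(pos = matrix(rnorm(30, sd = 3), ncol = 3),
                    deg_time = rep(0.001, 10))
  st3 <- sim_step(st3, 100)
  expect_equal(nrow(st3$field$pos), 0)
})

test_that("EGFs never end a step outside the domain or inside a cell", {
  cfg <- small_cfg(n_egfr = 2L, fate_enabled = FALSE,
                   mechanics_enabled = FALSE)
  st <- new_simulation(cfg, seed = 33, n_cells = 1)
  for (k in 1:40) {
    st <- sim_step(st, 10)
    if (nrow(st$field$pos) == 0) next
    r <- sqrt(rowSums(st$field$pos^2))
    expect_true(all(r <= cfg$domain_radius + 1e-9))
    d <- sweep(st$field$pos, 2, st$cells[[1]]$pos)
    expect_true(all(sqrt(rowSums(d^2)) >= st$cells[[1]]$radius - 1e-9))
  }
})

test_that("binding activates the nearest receptor and consumes the ligand", {
  cfg <- sim_config()
  s <- rng_stream(41)
  cell <- new_cell(cfg, stream = s)
  cell$receptors <- list(anchor = rbind(c(0, 0, 1), c(0, 1, 0)),
                         state = c(0L, 0L), soff = c(Inf, Inf))
  # no overlap anywhere -> no events
  far <- list(pos = matrix(c(0, 0, 50), ncol = 3), deg_time = 1e9)
  out <- attempt_binding(far, list(cell), clock = 0, s, cfg)
  expect_equal(nrow(out$events), 0)
  expect_identical(out$cells[[1]]$receptors$state, c(0L, 0L))

  # one EGF inside one receptor's reaction radius -> exactly one binding
  outer_z <- cfg$cell_radius + cfg$r_receptor
  near <- list(pos = matrix(c(0, 0, outer_z + 0.1), ncol = 3),
               deg_time = 1e9)
  out <- attempt_binding(near, list(cell), clock = 2, s, cfg)
  expect_equal(nrow(out$events), 1)
  expect_identical(out$cells[[1]]$receptors$state, c(1L, 0L))
  expect_gt(out$cells[[1]]$receptors$soff[1], 2)
  expect_equal(nrow(out$field$pos), 0)  # ligand left free diffusion

  # residence times drawn at the configured receptor off-rate: mean ~ 8 min
  soffs <- replicate(3000, {
    o <- attempt_binding(near, list(cell), clock = 0, s, cfg)
    o$cells[[1]]$receptors$soff[1]
  })
  expect_equal(mean(soffs), 8, tolerance = 0.06)
})

test_that("the receptor state machine is off -> on -> off and can rebind", {
  cfg <- sim_config()
  s <- rng_stream(43)
  cell <- new_cell(cfg, stream = s)
  cell$receptors <- list(anchor = matrix(c(0, 0, 1), ncol = 3), state = 1L,
                         soff = 10)
  # before the switch-off time nothing changes
  out <- release_expired_receptors(list(cell), clock = 9.99, config = cfg)
  expect_identical(out$cells[[1]]$receptors$state, 1L)
  # at the boundary (soff <= clock) the receptor switches off
  out <- release_expired_receptors(list(cell), clock = 10, config = cfg)
  expect_identical(out$cells[[1]]$receptors$state, 0L)
  # and it can bind again afterwards
  outer_z <- cfg$cell_radius + cfg$r_receptor
  near <- list(pos = matrix(c(0, 0, outer_z), ncol = 3), deg_time = 1e9)
  out2 <- attempt_binding(near, out$cells, clock = 11, s, cfg)
  expect_identical(out2$cells[[1]]$receptors$state, 1L)
})

test_that("receptor spheres stay clamped to a moving, growing cell", {
  cfg <- sim_config()
  s <- rng_stream(44)
  cell <- new_cell(cfg, stream = s)
  o1 <- receptor_centres(cell, cfg, "outer")
  cell$pos <- cell$pos + c(3, -1, 2)
  cell$radius <- cell$radius * 1.1
  o2 <- receptor_centres(cell, cfg, "outer")
  d <- sqrt(rowSums((o2 - sweep(o1, 2, c(3, -1, 2), "+"))^2))
  expect_true(all(d > 0))  # growth moved them radially outward
  r <- sqrt(rowSums(sweep(o2, 2, cell$pos)^2))
  expect_equal(r, rep(cell$radius + cfg$r_receptor, length(r)),
               tolerance = 1e-12)
})
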