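test_that("the repulsion force matches its closed form", {
  expect_equal(repulsion_force(7.5, h0 = 10, h1 = 5, K = 1), 1.0)
  expect_equal(repulsion_force(10, h0 = 10, h1 = 5, K = 1), 0)
  expect_equal(repulsion_force(12, h0 = 10, h1 = 5, K = 1), 0)
  # strictly decreasing on (h0 - h1, h0)
  h <- seq(5.05, 9.95, by = 0.05)
  f <- repulsion_force(h, 10, 5, 2.5)
  expect_true(all(diff(f) < 0))
  expect_error(repulsion_force(5, 10, 5, 1), "incompressibility")
  expect_error(repulsion_force(7, 10, 5, -1), "K")
  expect_error(repulsion_force(7, 10, 12, 1), "h1")
})

test_that("an isolated cell rests or decays geometrically", {
  cfg <- sim_config()
  s <- rng_stream(51)
  cell <- new_cell(cfg, stream = s)
  params <- list(mass = cfg$mass, friction = cfg$friction,
                 k_repulsion = cfg$k_repulsion)
  # at rest stays at rest
  out <- integrate_motion(list(cell), dt = 0.01, params)[[1]]
  expect_equal(out$pos, cell$pos)
  expect_equal(out$vel, c(0, 0, 0))
  # moving: velocity decays geometrically at the friction rate
  cell$vel <- c(2, 0, 0)
  v <- numeric(20)
  cells <- list(cell)
  for (k in 1:20) {
    cells <- integrate_motion(cells, dt = 0.01, params)
    v[k] <- cells[[1]]$vel[1]
  }
  ratios <- v[-1] / v[-20]
  expect_equal(ratios, rep(1 / (1 + cfg$friction * 0.01), 19),
               tolerance = 1e-12)
  expect_equal(ratios[1], exp(-cfg$friction * 0.01), tolerance = 0.01)
})

test_that("overlapping cells separate monotonically and keep the hard core", {
  st <- make_fixture("two-cell-overlap", seed = 3)
  h_prev <- 0
  hs <- numeric(60)
  for (k in 1:60) {
    st <- sim_step(st, 20)
    hs[k] <- sqrt(sum((st$cells[[1]]$pos - st$cells[[2]]$pos)^2))
  }
  h0 <- st$cells[[1]]$radius + st$cells[[2]]$radius
  h1 <- st$cells[[1]]$nucleus_radius + st$cells[[2]]$nucleus_radius
  expect_true(all(diff(hs) > -1e-9))
  expect_true(all(hs > h0 - h1))
  expect_gte(hs[60], h0 * 0.99)
})

test_that("the G1 checkpoint strictly exceeds the threshold", {
  cfg <- sim_config()
  s <- rng_stream(52)
  rule <- list(n_tf_star = 10, g1_duration = 660)
  mk <- function(n_on) {
    cell <- new_cell(cfg, stream = s)
    cell$cycle_clock <- 659.999
    idx <- which(cell$interior$species == 4L)[seq_len(n_on)]
    cell$interior$state[idx] <- 1L
    cell$interior$soff[idx] <- 1e9
    cell
  }
  # exactly at threshold -> apoptosis (strict "exceeds")
  out <- advance_cycle_and_fate(mk(10), dt = 0.005, rule)
  expect_identical(out$event, "apoptosis")
  expect_null(out$cell)
  # one above -> committed
  out <- advance_cycle_and_fate(mk(11), dt = 0.005, rule)
  expect_identical(out$event, "committed")
  expect_identical(out$cell$phase, "committed")
})

test_that("growth is linear in volume up to doubling", {
  cfg <- sim_config()
  s <- rng_stream(53)
  cell <- new_cell(cfg, stream = s)
  cell$phase <- "committed"
  cell$cycle_length <- 1440
  rule <- list(g1_duration = 660)
  R0 <- cell$radius
  cell$cycle_clock <- 660
  expect_equal(grow_cell(cell, rule)$radius, R0)
  cell$cycle_clock <- (660 + 1440) / 2
  expect_equal(grow_cell(cell, rule)$radius, R0 * 1.5^(1 / 3))
  cell$cycle_clock <- 1440
  expect_equal(grow_cell(cell, rule)$radius, R0 * 2^(1 / 3))
  cell$phase <- "g1"
  expect_error(grow_cell(cell, rule), "committed")
})

test_that("division conserves volume, separates daughters, and jitters cycles", {
  cfg <- sim_config()
  s <- rng_stream(54)
  cell <- new_cell(cfg, stream = s)
  cell$phase <- "committed"
  cell$cycle_clock <- cell$cycle_length
  # mother has doubled by division time
  V_div <- 2 * cell$birth_volume
  cell$radius <- (3 * V_div / (4 * pi))^(1 / 3)
  daughters <- divide_cell(cell, cfg, s)
  V <- vapply(daughters, function(d) 4 / 3 * pi * d$radius^3, numeric(1))
  expect_equal(sum(V), V_div, tolerance = 1e-9)
  # tangent, not overlapping, centres inside the doubled mother
  d12 <- sqrt(sum((daughters[[1]]$pos - daughters[[2]]$pos)^2))
  expect_equal(d12, daughters[[1]]$radius + daughters[[2]]$radius,
               tolerance = 1e-9)
  expect_true(all(vapply(daughters, function(d)
    sqrt(sum((d$pos - cell$pos)^2)) < cell$radius, logical(1))))
  expect_true(all(vapply(daughters, function(d) d$phase == "g1", logical(1))))
  expect_true(all(vapply(daughters, function(d) d$cycle_clock == 0,
                         logical(1))))

  # cycle lengths uniform on [21 h, 27 h]
  lens <- replicate(600, divide_cell(cell, cfg, s)[[1]]$cycle_length)
  ks <- suppressWarnings(ks.test(lens, "punif", 1260, 1620))
  expect_gt(ks$p.value, 0.01)
})

test_that("with no EGF every cell dies at its first checkpoint", {
  cfg <- sim_config(introduction_rate = 0, g1_duration = 5,
                    cycle_min = 30, cycle_max = 40, n_ras = 4L, n_raf = 2L,
                    n_erk = 2L, n_tf = 2L)
  st <- new_simulation(cfg, seed = 55, n_cells = 1)
  st <- sim_step(st, round(6 / cfg$dt))
  expect_length(st$cells, 0)
})

test_that("an always-divide threshold doubles the population each cycle", {
  cfg <- sim_config(introduction_rate = 0, n_tf_star = -1, g1_duration = 5,
                    cycle_min = 14, cycle_max = 16, n_ras = 4L, n_raf = 2L,
                    n_erk = 2L, n_tf = 2L, dt = 0.01)
  st <- new_simulation(cfg, seed = 56, n_cells = 1)
  pops <- sapply(1:3, function(k) {
    st <<- sim_step(st, round(16 / cfg$dt))
    length(st$cells)
  })
  expect_equal(pops, c(2, 4, 8))
})
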