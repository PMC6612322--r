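geom <- list(cell_radius = 5, nucleus_radius = 2.5)

test_that("molecule initialization places every species in its compartment", {
  s <- rng_stream(2)
  interior <- init_cell_molecules(geom, stream = s)
  expect_length(interior$species, 610)
  expect_equal(as.integer(table(interior$species)), c(200L, 60L, 300L, 50L))
  expect_true(all(interior$state == 0L))
  r <- sqrt(rowSums(interior$pos^2))
  cyto <- interior$species %in% 1:3
  expect_true(all(r[cyto] >= geom$nucleus_radius & r[cyto] <= geom$cell_radius))
  expect_true(all(r[interior$species == 4L] < geom$nucleus_radius))
  expect_error(
    init_cell_molecules(list(cell_radius = 2, nucleus_radius = 2), stream = s),
    "smaller")
})

test_that("mutations rescale only their own inactivation rate", {
  rates <- c(ras = 0.08, raf = 0.08, erk = 0.08, tf = 0.05)
  expect_identical(apply_mutation(mutation_profile(), rates), rates)
  kr <- apply_mutation(mutation_profile(kras = TRUE, kras_multiplier = 0.01),
                       rates)
  expect_equal(kr[["ras"]], 0.0008)
  expect_equal(kr[c("raf", "erk", "tf")], rates[c("raf", "erk", "tf")])
  br <- apply_mutation(mutation_profile(braf = TRUE), rates)
  expect_equal(br[["ras"]], rates[["ras"]])
  expect_equal(br[["raf"]], rates[["raf"]] * 0.01)
  # mean residence time scales inversely with the rate
  s <- rng_stream(5)
  expect_equal(mean(sample_exponential(kr[["ras"]], 2e4, s)),
               100 * 1 / rates[["ras"]], tolerance = 0.05)
  expect_error(mutation_profile(kras_multiplier = 1.5), "0, 1")
  expect_error(mutation_profile(n_egfr = 0), "n_egfr")
})

test_that("without an activation source the interior stays silent", {
  cfg <- sim_config()
  s <- rng_stream(3)
  interior <- init_cell_molecules(geom, c(ras = 30L, raf = 10L, erk = 20L,
                                          tf = 5L), s)
  rates <- base_rates(cfg)
  none <- matrix(numeric(0), ncol = 3)
  for (k in 1:50)
    interior <- step_interior(interior, none, rates, geom, cfg$dt,
                              (k - 1) * cfg$dt, s, cfg)
  expect_true(all(interior$state == 0L))
  expect_identical(count_active_tf(interior), 0L)
})

test_that("a Ras molecule overlapping an active G-protein sphere fires", {
  cfg <- sim_config(d_protein = 1e-9)  # keep it in place
  s <- rng_stream(4)
  interior <- init_cell_molecules(geom, c(ras = 1L, raf = 0L, erk = 0L,
                                          tf = 0L), s)
  inner <- matrix(c(0, 0, geom$cell_radius - cfg$r_receptor), ncol = 3,
                  byrow = TRUE)
  interior$pos[1, ] <- inner[1, ] + c(0, 0, -cfg$r_receptor)  # inside sphere
  out <- step_interior(interior, inner, base_rates(cfg), geom, cfg$dt, 0, s,
                       cfg)
  expect_identical(out$state[1], 1L)
  expect_gt(out$soff[1], 0)
})

test_that("counts are conserved and compartments respected over time", {
  cfg <- sim_config()
  s <- rng_stream(6)
  interior <- init_cell_molecules(geom, stream = s)
  inner <- matrix(c(0, 0, geom$cell_radius - cfg$r_receptor), ncol = 3)
  rates <- base_rates(cfg)
  for (k in 1:400) {
    interior <- step_interior(interior, inner, rates, geom, cfg$dt,
                              (k - 1) * cfg$dt, s, cfg)
  }
  expect_equal(as.integer(table(interior$species)), c(200L, 60L, 300L, 50L))
  r <- sqrt(rowSums(interior$pos^2))
  sp <- interior$species
  on <- interior$state == 1L
  tol <- 1e-9
  # Ras, Raf: cytoplasm
  expect_true(all(r[sp %in% 1:2] >= geom$nucleus_radius - tol))
  expect_true(all(r[sp %in% 1:2] <= geom$cell_radius + tol))
  # TF: nucleus
  expect_true(all(r[sp == 4L] <= geom$nucleus_radius + tol))
  # ERK: whole cell, and some activity reached ERK by now
  expect_true(all(r[sp == 3L] <= geom$cell_radius + tol))
  expect_gt(sum(on), 0)
})

test_that("lowering an inactivation rate raises the active level", {
  cfg_slow <- sim_config(k_inact_ras = 0.02)
  cfg_fast <- sim_config(k_inact_ras = 0.5)
  level <- function(cfg, seed) {
    runs <- run_single_cell("normal", cfg, replicates = 6L, t_end = 20,
                            seed = seed, record_every_min = 20,
                            receptor_on_min = 20)
    mean(runs$ras[runs$time > 0])
  }
  expect_gt(level(cfg_slow, 8), level(cfg_fast, 8))
})

test_that("division splits every species exactly in half", {
  s <- rng_stream(9)
  interior <- init_cell_molecules(geom, stream = s)
  # switch a few TFs on with known residence times
  tf_idx <- which(interior$species == 4L)[1:7]
  interior$state[tf_idx] <- 1L
  interior$soff[tf_idx] <- 123.4
  halves <- halve_on_division(interior, geom, s)
  c1 <- table(factor(halves[[1]]$species, levels = 1:4))
  c2 <- table(factor(halves[[2]]$species, levels = 1:4))
  expect_equal(as.integer(c1), c(100L, 30L, 150L, 25L))
  expect_equal(as.integer(c2), c(100L, 30L, 150L, 25L))
  # active TFs conserved with their switch-off times
  on_tf <- function(h) sum(h$state == 1L & h$species == 4L)
  expect_identical(on_tf(halves[[1]]) + on_tf(halves[[2]]), 7L)
  expect_true(all(halves[[1]]$soff[halves[[1]]$state == 1L] == 123.4))
  # positions are re-drawn inside the daughter's compartments
  for (h in halves) {
    r <- sqrt(rowSums(h$pos^2))
    expect_true(all(r[h$species == 4L] <= geom$nucleus_radius))
    expect_true(all(r[h$species %in% 1:2] >= geom$nucleus_radius))
  }
  # odd counts split by fair coin but always conserve the total
  odd <- init_cell_molecules(geom, c(ras = 7L, raf = 0L, erk = 0L, tf = 0L),
                             s)
  tot <- replicate(20, {
    h <- halve_on_division(odd, geom, s)
    c(sum(h[[1]]$species == 1L), sum(h[[2]]$species == 1L))
  })
  expect_true(all(colSums(tot) == 7L))
  expect_true(all(tot >= 3L & tot <= 4L))
})

test_that("the well-mixed limit matches a mass-action Gillespie oracle", {
  # Fast diffusion in a small cell decorrelates positions between steps, so
  # the overlap scheme becomes a binomial tau-leap of the mass-action
  # cascade with per-pair rate p/dt, p the uniform-overlap probability.
  Rc <- 2
  Rn <- 0.5
  rbd <- 0.25
  rrec <- 0.4
  dt <- 0.01
  cfg <- sim_config(cell_radius = Rc, nucleus_radius = Rn, r_bd = rbd,
                    r_receptor = rrec, d_protein = 2000, dt = dt,
                    n_ras = 40L, n_raf = 30L, n_erk = 30L, n_tf = 0L,
                    k_inact_ras = 0.5, k_inact_raf = 0.5, k_inact_erk = 0.5,
                    field_enabled = FALSE, mechanics_enabled = FALSE,
                    fate_enabled = FALSE)
  t_end <- 6
  reps <- 120L
  runs <- run_single_cell("normal", cfg, replicates = reps, t_end = t_end,
                          seed = 31, record_every_min = 2,
                          receptor_on_min = 1e9)
  bd <- ensemble_mean(runs)

  set.seed(99)
  p_pair <- mc_pair_overlap_prob(Rn, Rc, 2 * rbd)
  p_rec <- mc_point_overlap_prob(Rn, Rc, Rc - rrec, rrec + rbd)
  times <- bd$time[bd$time > 0]
  ssa <- ssa_ensemble(400L, counts = c(40, 30, 30), n_rec = 1,
                      k_act = c(p_rec / dt, p_pair / dt, p_pair / dt),
                      k_off = c(0.5, 0.5, 0.5), t_end = t_end + 1,
                      times = times)
  for (j in 1:3) {
    bdv <- bd[bd$time > 0, c("ras", "raf", "erk")][, j]
    # Monte-Carlo tolerance: generous absolute-plus-relative band
    expect_equal(bdv, ssa[, j], tolerance = 0.15,
                 ignore_attr = TRUE)
  }
})
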