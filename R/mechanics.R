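#' Pairwise repulsive force magnitude
#'
#' Centre-based cell mechanics: two cells at centre distance `h` repel with
#' `K (h0 - h) / (h - (h0 - h1))` for `h0 - h1 < h < h0` and zero for
#' `h >= h0`, where `h0` is the sum of their radii and `h1` the sum of their
#' incompressible (nuclear) parts. The force diverges as `h` approaches
#' `h0 - h1`, which keeps nuclei from overlapping.
#'
#' @param h centre distance(s), um.
#' @param h0 sum of the two radii, um.
#' @param h1 sum of the two incompressible radii, um, `0 < h1 < h0`.
#' @param K positive force scale.
#' @return Force magnitude(s), directed along the centre line, pushing apart.
#' @export
repulsion_force <- function(h, h0, h1, K) {
  if (K <= 0) stop("`K` must be positive", call. = FALSE)
  if (h1 <= 0 || h1 >= h0) stop("need 0 < h1 < h0", call. = FALSE)
  if (any(h <= h0 - h1))
    stop("incompressibility violated: h must exceed h0 - h1", call. = FALSE)
  ifelse(h >= h0, 0, K * (h0 - h) / (h - (h0 - h1)))
}

#' Create a cell
#'
#' A cell is a soft sphere with an incompressible nucleus, its own interior
#' molecules, membrane receptor clusters, a cycle clock, and a mutation
#' profile.
#'
#' @param config an `egfr_config`.
#' @param id integer cell id.
#' @param pos position of the centre (um).
#' @param stream an [rng_stream()].
#' @param profile a [mutation_profile()].
#' @return A cell object.
#' @export
new_cell <- function(config = sim_config(), id = 1L, pos = c(0, 0, 0),
                     stream, profile = named_profile("normal", config)) {
  check_stream(stream)
  geom <- list(cell_radius = config$cell_radius,
               nucleus_radius = config$nucleus_radius)
  counts <- c(ras = config$n_ras, raf = config$n_raf, erk = config$n_erk,
              tf = config$n_tf)
  list(id = as.integer(id), pos = as.double(pos), vel = c(0, 0, 0),
       radius = config$cell_radius, nucleus_radius = config$nucleus_radius,
       birth_volume = 4 / 3 * pi * config$cell_radius^3,
       phase = "g1", cycle_clock = 0,
       cycle_length = config$cycle_min +
         (config$cycle_max - config$cycle_min) * cpp_runif(stream, 1L),
       mutation = unclass(profile),
       interior = init_cell_molecules(geom, counts, stream),
       receptors = make_receptors(profile$n_egfr, stream))
}

#' Advance the cycle clock and decide fate at the G1 checkpoint
#'
#' At the end of G1 the cell counts its active transcription factors: if the
#' count strictly exceeds the threshold `n_tf_star` the cell commits to
#' growth and division, otherwise it dies by apoptosis. A committed cell
#' divides once its cycle completes.
#'
#' @param cell a cell object.
#' @param dt time step (min).
#' @param rule list with `n_tf_star` and `g1_duration` (min).
#' @return List with the updated `cell` (NULL on apoptosis) and `event`, one
#'   of `"none"`, `"committed"`, `"apoptosis"`, `"divide"`.
#' @export
advance_cycle_and_fate <- function(cell, dt, rule) {
  cell$cycle_clock <- cell$cycle_clock + dt
  event <- "none"
  if (cell$phase == "g1" && cell$cycle_clock >= rule$g1_duration) {
    if (count_active_tf(cell$interior) > rule$n_tf_star) {
      cell$phase <- "committed"
      event <- "committed"
    } else {
      return(list(cell = NULL, event = "apoptosis"))
    }
  }
  if (cell$phase == "committed" && cell$cycle_clock >= cell$cycle_length)
    event <- "divide"
  list(cell = cell, event = event)
}

#' Grow a committed cell
#'
#' Volume increases linearly from the birth volume at commitment (end of G1)
#' to twice the birth volume at the end of the cycle; the radius follows as
#' `(3V / 4 pi)^(1/3)`. The nucleus is incompressible and does not grow.
#'
#' @param cell a committed cell.
#' @param rule list with `g1_duration`.
#' @return The cell with updated radius.
#' @export
grow_cell <- function(cell, rule) {
  if (cell$phase != "committed") stop("only committed cells grow",
                                      call. = FALSE)
  frac <- (cell$cycle_clock - rule$g1_duration) /
    (cell$cycle_length - rule$g1_duration)
  frac <- min(max(frac, 0), 1)
  V <- cell$birth_volume * (1 + frac)
  cell$radius <- (3 * V / (4 * pi))^(1 / 3)
  cell
}

#' Divide a cell
#'
#' Two daughters of half the mother's division-time volume appear
#' symmetrically about the mother's centre along a uniformly random axis,
#' tangent to each other. Interiors are split with [halve_on_division()];
#' each daughter gets a fresh uniform layout of its genotype's receptor
#' count, a cycle length drawn uniformly from `[cycle_min, cycle_max]`, and
#' starts in G1.
#'
#' @param cell a committed cell at the end of its cycle.
#' @param config an `egfr_config`.
#' @param stream an [rng_stream()].
#' @param next_ids integer vector of two ids for the daughters.
#' @return List of two cell objects.
#' @export
divide_cell <- function(cell, config = sim_config(), stream,
                        next_ids = cell$id * 2L + c(0L, 1L)) {
  check_stream(stream)
  r_d <- (3 * cell$birth_volume / (4 * pi))^(1 / 3)
  axis <- drop(cpp_runit(stream, 1L))
  geom <- list(cell_radius = r_d, nucleus_radius = cell$nucleus_radius)
  halves <- halve_on_division(cell$interior, geom, stream)
  lapply(1:2, function(d) {
    daughter <- cell
    daughter$id <- as.integer(next_ids[d])
    daughter$pos <- cell$pos + (if (d == 1) 1 else -1) * r_d * axis
    daughter$radius <- r_d
    daughter$birth_volume <- 4 / 3 * pi * r_d^3
    daughter$phase <- "g1"
    daughter$cycle_clock <- 0
    daughter$cycle_length <- config$cycle_min +
      (config$cycle_max - config$cycle_min) * cpp_runif(stream, 1L)
    daughter$interior <- halves[[d]]
    daughter$receptors <- make_receptors(cell$mutation$n_egfr, stream)
    daughter
  })
}

#' Integrate cell motion for one time step
#'
#' Newtonian dynamics with inertia retained: `m x'' + m mu x' = sum(f_ij)`,
#' advanced by semi-implicit Euler. Forces are the pairwise repulsions of
#' [repulsion_force()].
#'
#' @param cells list of cell objects.
#' @param dt time step (min).
#' @param params list with `mass`, `friction`, `k_repulsion`.
#' @return The cells with updated velocities and positions.
#' @export
integrate_motion <- function(cells, dt, params) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  n <- length(cells)
  if (n == 0) return(cells)
  f <- matrix(0, n, 3)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- cells[[i]]$pos - cells[[j]]$pos
        h <- sqrt(sum(d^2))
        h0 <- cells[[i]]$radius + cells[[j]]$radius
        if (h >= h0) next
        h1 <- cells[[i]]$nucleus_radius + cells[[j]]$nucleus_radius
        heff <- max(h, h0 - h1 + 1e-9)
        fm <- params$k_repulsion * (h0 - heff) / (heff - (h0 - h1))
        u <- if (h < 1e-9) c(0, 0, 1) else d / h
        f[i, ] <- f[i, ] + fm * u
        f[j, ] <- f[j, ] - fm * u
      }
    }
  }
  denom <- 1 + params$friction * dt
  for (i in seq_len(n)) {
    cells[[i]]$vel <- (cells[[i]]$vel + dt * f[i, ] / params$mass) / denom
    cells[[i]]$pos <- cells[[i]]$pos + dt * cells[[i]]$vel
  }
  cells
}
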