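#' Create a simulation state
#'
#' A state bundles the global clock, the extracellular field, the cells and
#' the configuration, and is advanced by [sim_step()]. All subsystems share
#' the clock: the operator-split step synchronizes them at its end.
#'
#' @param config an `egfr_config`.
#' @param seed integer master seed; per-subsystem streams are derived from
#'   it, so adding a cell does not perturb the draws of the others.
#' @param n_cells number of initial cells (placed at the domain centre).
#' @param profile a [mutation_profile()] for the initial cells.
#' @return A list of class `egfr_state`.
#' @export
new_simulation <- function(config = sim_config(), seed = 1L, n_cells = 1L,
                           profile = named_profile("normal", config)) {
  init <- rng_stream(seed, stream_id = 99L)
  cells <- lapply(seq_len(n_cells), function(i)
    new_cell(config, id = i, pos = c(0, 0, 0), stream = init,
             profile = profile))
  structure(list(clock = 0, next_id = n_cells + 1L, seed = as.double(seed),
                 epoch = 0L, config = config, field = new_field(config),
                 cells = cells),
            class = "egfr_state")
}

#' @export
print.egfr_state <- function(x, ...) {
  alive <- sum(vapply(x$cells, function(c) c$phase != "corpse", logical(1)))
  cat(sprintf("<egfr_state> t = %.3f min, %d cell(s), %d free EGF\n",
              x$clock, alive, nrow(x$field$pos)))
  invisible(x)
}

#' Advance a simulation by operator-split steps
#'
#' One step propagates, in the configured order (default: field, then every
#' cell interior, then cell mechanics): (1) EGF introduction, diffusion with
#' reflection, degradation, receptor binding and receptor release; (2) the
#' intracellular Brownian-Dynamics cascade of every living cell; (3) cycle
#' and fate rules, growth, division, and centre-based motion. The clock then
#' advances by `dt`.
#'
#' @param state an `egfr_state`.
#' @param n_steps number of steps of `config$dt` to take.
#' @param record_every record the population and summed active species counts
#'   every this many steps (0 = no records).
#' @return The updated state; when recording, the attribute `"records"`
#'   holds a data frame with columns `time`, `n_cells`, `n_egf`, `ras`,
#'   `raf`, `erk`, `tf`.
#' @export
sim_step <- function(state, n_steps = 1L, record_every = 0L) {
  stopifnot(inherits(state, "egfr_state"))
  out <- cpp_engine_run(unclass(state), as.integer(n_steps),
                        as.integer(record_every))
  new_state <- structure(out$state, class = "egfr_state")
  new_state$config <- state$config
  if (!is.null(out$records)) attr(new_state, "records") <- out$records
  new_state
}

state_records <- function(state) attr(state, "records")

derive_seeds <- function(seed, n) {
  # deterministic per-replicate seeds below 2^31
  (as.double(seed) * 2654435761 + 97 * seq_len(n)) %% 2147483647
}

single_cell_state <- function(config, seed, profile, anchors, on_for) {
  cfg <- sim_config(modifyList(unclass(config), list(
    field_enabled = FALSE, mechanics_enabled = FALSE, fate_enabled = FALSE)))
  state <- new_simulation(cfg, seed = seed, n_cells = 1L, profile = profile)
  n <- nrow(anchors)
  state$cells[[1]]$receptors <- list(anchor = anchors,
                                     state = rep(1L, n),
                                     soff = rep(on_for, n))
  state
}

#' Single-cell mutation scenario
#'
#' One cell, no extracellular dynamics: a single receptor cluster starts
#' active and switches off after exactly 8 min (the mean receptor residence
#' time). Records the active counts of Ras, Raf, ERK and TF over time for an
#' ensemble of replicates, for a normal cell or one carrying K-Ras and/or
#' B-Raf mutations.
#'
#' @param profile `"normal"`, `"kras"`, `"braf"` or `"kras_braf"`, or a
#'   [mutation_profile()].
#' @param config an `egfr_config`.
#' @param replicates ensemble size.
#' @param t_end simulated time (min).
#' @param seed integer seed.
#' @param record_every_min recording interval (min).
#' @param receptor_on_min how long the receptor stays active (min).
#' @return A tidy data frame: `replicate`, `time`, `ras`, `raf`, `erk`, `tf`.
#' @export
run_single_cell <- function(profile = "normal", config = sim_config(),
                            replicates = 25L, t_end = 120, seed = 1L,
                            record_every_min = 0.5, receptor_on_min = 8) {
  if (is.character(profile)) profile <- named_profile(profile, config)
  seeds <- derive_seeds(seed, replicates)
  n_steps <- round(t_end / config$dt)
  rec_every <- max(1L, round(record_every_min / config$dt))
  anchors <- matrix(c(0, 0, 1), ncol = 3)
  out <- lapply(seq_len(replicates), function(r) {
    st <- single_cell_state(config, seeds[r], profile, anchors,
                            receptor_on_min)
    st <- sim_step(st, n_steps, record_every = rec_every)
    rec <- state_records(st)
    data.frame(replicate = r, time = rec$time, ras = rec$ras, raf = rec$raf,
               erk = rec$erk, tf = rec$tf)
  })
  do.call(rbind, out)
}

#' Receptor-placement scenario
#'
#' Two receptor clusters start active for 8 min each, either adjacent (a
#' small angular separation) or at opposite poles of the cell. When the two
#' G-protein sites are close together they compete for the same pool of
#' nearby inactive Ras, so the antipodal placement drives a higher
#' transcription-factor response.
#'
#' @param placement `"adjacent"` or `"antipodal"`.
#' @param adjacent_angle angular separation (degrees) of the adjacent pair.
#' @inheritParams run_single_cell
#' @return A tidy data frame as in [run_single_cell()], plus a `placement`
#'   column.
#' @export
run_receptor_placement <- function(placement = c("adjacent", "antipodal"),
                                   config = sim_config(), replicates = 25L,
                                   t_end = 120, seed = 1L,
                                   record_every_min = 0.5,
                                   receptor_on_min = 8,
                                   adjacent_angle = 20) {
  placement <- match.arg(placement)
  half <- if (placement == "adjacent") adjacent_angle * pi / 360 else pi / 2
  anchors <- rbind(c(sin(half), 0, cos(half)),
                   c(-sin(half), 0, cos(half)))
  profile <- named_profile("normal", config)
  seeds <- derive_seeds(seed, replicates)
  n_steps <- round(t_end / config$dt)
  rec_every <- max(1L, round(record_every_min / config$dt))
  out <- lapply(seq_len(replicates), function(r) {
    st <- single_cell_state(config, seeds[r], profile, anchors,
                            receptor_on_min)
    st <- sim_step(st, n_steps, record_every = rec_every)
    rec <- state_records(st)
    data.frame(placement = placement, replicate = r, time = rec$time,
               ras = rec$ras, raf = rec$raf, erk = rec$erk, tf = rec$tf)
  })
  do.call(rbind, out)
}

#' Tumour-growth scenario
#'
#' Starts from one tumour-initiating cell at the centre of the domain with
#' the full multiscale coupling: EGFs stream in from the boundary, bind the
#' cell's receptors, drive its cascade, and the transcription-factor
#' checkpoint decides division or apoptosis. Records the living-cell count
#' over time.
#'
#' @param config an `egfr_config`; set `n_egfr` for EGFR overexpression.
#' @param profile a [mutation_profile()] or profile name.
#' @param horizon_min simulated horizon (min).
#' @param seed integer seed.
#' @param record_every_min recording interval (min).
#' @param warm_field prefill the field at its cell-free stationary count
#'   instead of starting empty.
#' @return List with `population` (data frame `time`, `n_cells`, `n_egf`)
#'   and `state` (the final state, for snapshots).
#' @export
run_tumour <- function(config = sim_config(), profile = "normal",
                       horizon_min = 2880, seed = 1L, record_every_min = 30,
                       warm_field = TRUE) {
  if (is.character(profile)) profile <- named_profile(profile, config)
  profile$n_egfr <- config$n_egfr
  state <- new_simulation(config, seed = seed, n_cells = 1L,
                          profile = profile)
  if (warm_field) {
    stream <- rng_stream(seed, stream_id = 98L)
    n0 <- round(config$introduction_rate / config$degradation_rate)
    state$field <- list(
      pos = uniform_point_in_shell(r_outer = config$domain_radius, n = n0,
                                   stream = stream),
      deg_time = sample_exponential(config$degradation_rate, n0, stream))
  }
  n_steps <- round(horizon_min / config$dt)
  rec_every <- max(1L, round(record_every_min / config$dt))
  state <- sim_step(state, n_steps, record_every = rec_every)
  rec <- state_records(state)
  list(population = rec[, c("time", "n_cells", "n_egf")], state = state)
}

#' Ensemble mean of scenario output
#'
#' @param runs data frame from [run_single_cell()] or
#'   [run_receptor_placement()].
#' @return Data frame of per-time ensemble means of the active counts.
#' @export
ensemble_mean <- function(runs) {
  aggregate(runs[, c("ras", "raf", "erk", "tf")],
            by = list(time = runs$time), FUN = mean)
}

#' Peak time of a smoothed ensemble trajectory
#'
#' Smooths the ensemble-mean curve with a centred moving average and returns
#' the time of its maximum.
#'
#' @param time,value numeric vectors (minutes, counts).
#' @param window smoothing window (min).
#' @return Peak time (min).
#' @export
peak_time <- function(time, value, window = 10) {
  dt <- stats::median(diff(time))
  k <- max(1L, round(window / dt))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(value, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- -Inf
  time[which.max(sm)]
}

#' Time-step convergence study
#'
#' Repeats the single-cell scenario over a ladder of time steps and reports
#' the ensemble mean and standard error of the active Ras, Raf and ERK
#' counts at a fixed measurement time, ten replicates each by default. The
#' largest time step whose means are statistically indistinguishable from
#' those of the smallest tested step is the converged step.
#'
#' @param dts time steps to test (min).
#' @param config an `egfr_config`.
#' @param replicates replicates per time step.
#' @param t_measure measurement time (min).
#' @param seed integer seed.
#' @return Data frame with one row per (dt, species): mean and standard
#'   error of the active count at `t_measure`.
#' @export
run_convergence <- function(dts = c(0.02, 0.01, 0.005, 0.0025, 0.001),
                            config = sim_config(), replicates = 10L,
                            t_measure = 30, seed = 1L) {
  out <- lapply(dts, function(dt) {
    cfg <- sim_config(modifyList(unclass(config), list(dt = dt)))
    runs <- run_single_cell("normal", cfg, replicates = replicates,
                            t_end = t_measure, seed = seed,
                            record_every_min = t_measure)
    last <- runs[runs$time == max(runs$time), ]
    do.call(rbind, lapply(c("ras", "raf", "erk"), function(sp) {
      data.frame(dt = dt, species = sp, mean = mean(last[[sp]]),
                 se = stats::sd(last[[sp]]) / sqrt(nrow(last)))
    }))
  })
  do.call(rbind, out)
}

#' Largest converged time step of a convergence study
#'
#' Compares every tested step against the smallest one with a Welch-type
#' z-statistic per species; a step is converged when no species differs by
#' more than `z_crit` combined standard errors.
#'
#' @param conv output of [run_convergence()].
#' @param z_crit critical z value.
#' @return The largest converged dt (min).
#' @export
converged_dt <- function(conv, z_crit = 3) {
  ref <- conv[conv$dt == min(conv$dt), ]
  dts <- sort(unique(conv$dt), decreasing = TRUE)
  for (dt in dts) {
    cur <- conv[conv$dt == dt, ]
    z <- abs(cur$mean - ref$mean[match(cur$species, ref$species)]) /
      sqrt(cur$se^2 + ref$se[match(cur$species, ref$species)]^2 + 1e-12)
    if (all(z <= z_crit)) return(dt)
  }
  min(conv$dt)
}
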