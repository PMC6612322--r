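#' Create an empty extracellular field
#'
#' The field holds the free EGF particles of the spherical domain. EGFs are
#' introduced on a thin outer shell at a constant rate and removed at an
#' exponentially distributed degradation time, so in a cell-free domain the
#' long-run mean count equals `introduction_rate / degradation_rate` (about
#' 660 at the defaults).
#'
#' @param config an `egfr_config`.
#' @return A field object: list with `pos` (n x 3) and `deg_time` (absolute
#'   clock times, min).
#' @export
new_field <- function(config = sim_config()) {
  list(pos = matrix(numeric(0), ncol = 3), deg_time = numeric(0))
}

#' Introduce new EGF particles at the domain boundary
#'
#' A Poisson(`introduction_rate * dt`) number of EGFs is placed uniformly in
#' the outer introduction layer; each receives an absolute degradation time
#' `clock + Exp(degradation_rate)`.
#'
#' @param field a field object.
#' @param dt time step (min).
#' @param clock current time (min).
#' @param stream an [rng_stream()].
#' @param config an `egfr_config`.
#' @return The updated field.
#' @export
introduce_egf <- function(field, dt, clock, stream, config = sim_config()) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  check_stream(stream)
  n <- cpp_rpois(stream, config$introduction_rate * dt, 1L)
  if (n > 0) {
    pos <- uniform_point_in_shell(
      r_inner = max(0, config$domain_radius - config$shell_thickness),
      r_outer = config$domain_radius, n = n, stream = stream)
    field$pos <- rbind(field$pos, pos)
    field$deg_time <- c(field$deg_time,
                        clock + sample_exponential(config$degradation_rate,
                                                   n, stream))
  }
  field
}

# reflect points out of every cell body (mirror across the membrane),
# iterating so a reflection out of one cell cannot leave a point inside
# another, then back into the domain ball
reflect_off_cells <- function(pos, cells, config) {
  if (nrow(pos) == 0 || length(cells) == 0) return(pos)
  for (it in 1:8) {
    viol <- FALSE
    for (cell in cells) {
      d <- sweep(pos, 2, cell$pos)
      r <- sqrt(rowSums(d^2))
      inside <- r < cell$radius
      if (any(inside)) {
        viol <- TRUE
        sc <- (2 * cell$radius - r[inside]) / pmax(r[inside], 1e-9)
        pos[inside, ] <- rep(cell$pos, each = sum(inside)) +
          d[inside, , drop = FALSE] * sc
      }
    }
    if (!viol) break
    pos <- reflect_in_shell(pos, r_outer = config$domain_radius)
  }
  pos
}

#' Diffuse, reflect and degrade the free EGF particles
#'
#' Every unbound EGF takes a Brownian step with `d_egf`, is reflected at the
#' outer domain boundary and off every cell membrane, and is removed once its
#' degradation time has passed.
#'
#' @inheritParams introduce_egf
#' @param cells list of cell objects (only `pos` and `radius` are used).
#' @return The updated field.
#' @export
step_field <- function(field, cells, dt, clock, stream,
                       config = sim_config()) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  check_stream(stream)
  if (nrow(field$pos) > 0) {
    pos <- brownian_step(field$pos, config$d_egf, dt, stream)
    pos <- reflect_in_shell(pos, r_outer = config$domain_radius)
    pos <- reflect_off_cells(pos, cells, config)
    keep <- field$deg_time > clock
    field$pos <- pos[keep, , drop = FALSE]
    field$deg_time <- field$deg_time[keep]
  }
  field
}

#' Lay receptor clusters uniformly on a cell membrane
#'
#' Each EGFR cluster is a pair of spheres clamped to the membrane along a
#' uniformly random anchor direction: the ligand-binding sphere outside, the
#' G-protein sphere inside. Receptors start 'off'.
#'
#' @param n number of clusters.
#' @param stream an [rng_stream()].
#' @return A receptor set: list with `anchor` (n x 3 unit vectors), `state`
#'   (0/1) and `soff` (absolute switch-off times).
#' @export
make_receptors <- function(n, stream) {
  check_stream(stream)
  list(anchor = cpp_runit(stream, as.integer(n)),
       state = integer(n), soff = rep(Inf, n))
}

#' Receptor sphere centres for a cell
#'
#' Both sphere centres lie on the anchor axis through the cell centre
#' (perpendicular to the membrane): the outer sphere at
#' `radius + r_receptor`, the inner at `radius - r_receptor`. Because the
#' centres are recomputed from the current cell position and radius, the
#' clamped spheres track cell motion and growth.
#'
#' @param cell a cell object.
#' @param config an `egfr_config`.
#' @param which `"outer"` (world coordinates) or `"inner"` (cell-local).
#' @param active_only keep only 'on' receptors.
#' @return An m x 3 matrix of centres.
#' @export
receptor_centres <- function(cell, config = sim_config(),
                             which = c("outer", "inner"),
                             active_only = FALSE) {
  which <- match.arg(which)
  rec <- cell$receptors
  sel <- if (active_only) rec$state == 1L else rep(TRUE, length(rec$state))
  an <- rec$anchor[sel, , drop = FALSE]
  if (which == "outer") {
    sweep(an * (cell$radius + config$r_receptor), 2, cell$pos, "+")
  } else {
    an * (cell$radius - config$r_receptor)
  }
}

#' Bind free EGFs to overlapping inactive receptors
#'
#' An unbound EGF within `r_receptor + r_egf` of an 'off' receptor's outer
#' sphere centre binds it: the EGF leaves free diffusion, the receptor turns
#' 'on' and draws an exponential residence time at rate `k_off_receptor`.
#' When several overlaps compete, the globally nearest pairs win (each EGF
#' binds at most one receptor per step and vice versa).
#'
#' @inheritParams step_field
#' @return List with updated `field`, `cells`, and a data frame `events`
#'   (columns `cell`, `receptor`, `distance`).
#' @export
attempt_binding <- function(field, cells, clock, stream,
                            config = sim_config()) {
  check_stream(stream)
  sig <- config$r_receptor + config$r_egf
  cand <- list()
  if (nrow(field$pos) > 0) {
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      off <- which(cell$receptors$state == 0L)
      if (!length(off)) next
      centres <- receptor_centres(cell, config, "outer")
      for (ri in off) {
        d <- sweep(field$pos, 2, centres[ri, ])
        r <- sqrt(rowSums(d^2))
        hit <- which(r < sig)
        for (e in hit)
          cand[[length(cand) + 1L]] <- data.frame(
            cell = ci, receptor = ri, egf = e, distance = r[e])
      }
    }
  }
  events <- data.frame(cell = integer(0), receptor = integer(0),
                       distance = numeric(0))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$distance, cand$egf, cand$cell, cand$receptor), ]
    used_egf <- logical(nrow(field$pos))
    for (q in seq_len(nrow(cand))) {
      ci <- cand$cell[q]; ri <- cand$receptor[q]; e <- cand$egf[q]
      if (used_egf[e] || cells[[ci]]$receptors$state[ri] == 1L) next
      cells[[ci]]$receptors$state[ri] <- 1L
      cells[[ci]]$receptors$soff[ri] <-
        clock + sample_exponential(config$k_off_receptor, 1L, stream)
      used_egf[e] <- TRUE
      events <- rbind(events, data.frame(cell = ci, receptor = ri,
                                         distance = cand$distance[q]))
    }
    field$pos <- field$pos[!used_egf, , drop = FALSE]
    field$deg_time <- field$deg_time[!used_egf]
  }
  list(field = field, cells = cells, events = events)
}

#' Switch off receptors past their residence time
#'
#' Every 'on' receptor whose switch-off time has been reached returns to
#' 'off' and can bind again in a later [attempt_binding()]. Its bound EGF is
#' consumed (internalization-like); with `egf_rerelease = TRUE` it is instead
#' re-released just outside the receptor.
#'
#' @inheritParams attempt_binding
#' @param field a field object, required only when re-release is configured.
#' @return List with updated `cells` and `field`.
#' @export
release_expired_receptors <- function(cells, clock, field = NULL,
                                      stream = NULL,
                                      config = sim_config()) {
  for (ci in seq_along(cells)) {
    rec <- cells[[ci]]$receptors
    exp_now <- which(rec$state == 1L & rec$soff <= clock)
    if (!length(exp_now)) next
    rec$state[exp_now] <- 0L
    rec$soff[exp_now] <- Inf
    if (isTRUE(config$egf_rerelease) && !is.null(field)) {
      check_stream(stream)
      outer <- receptor_centres(cells[[ci]], config, "outer")
      off <- (config$r_receptor + config$r_egf) *
        cells[[ci]]$receptors$anchor[exp_now, , drop = FALSE]
      field$pos <- rbind(field$pos, outer[exp_now, , drop = FALSE] + off)
      field$deg_time <- c(field$deg_time,
                          clock + sample_exponential(config$degradation_rate,
                                                     length(exp_now), stream))
    }
    cells[[ci]]$receptors <- rec
  }
  list(cells = cells, field = field)
}
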