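#' Create a reproducible random stream
#'
#' Each subsystem of the simulator (the extracellular field, every cell, the
#' mechanics) draws from its own stream so that adding one object never
#' perturbs the draws of another. Identical seed and identical call sequence
#' give identical draws.
#'
#' @param seed integer master seed.
#' @param stream_id integer substream identifier.
#' @return An opaque stream object of class `rng_stream`.
#' @export
rng_stream <- function(seed, stream_id = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  structure(cpp_rng_new(as.double(seed), as.double(stream_id)),
            class = "rng_stream", seed = seed, stream_id = stream_id)
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream> seed", attr(x, "seed"), "substream",
      attr(x, "stream_id"), "\n")
  invisible(x)
}

check_stream <- function(stream) {
  if (!inherits(stream, "rng_stream"))
    stop("`stream` must be an rng_stream (see rng_stream())", call. = FALSE)
  stream
}

#' Sample exponential waiting times
#'
#' Waiting times (EGF degradation, receptor and protein residence times) are
#' exponentially distributed with parameter equal to the corresponding
#' reaction rate.
#'
#' @param rate rate parameter in 1/min; must be positive.
#' @param n number of draws.
#' @param stream an [rng_stream()].
#' @return Numeric vector of non-negative waiting times in minutes.
#' @export
sample_exponential <- function(rate, n = 1L, stream) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive finite number", call. = FALSE)
  check_stream(stream)
  cpp_rexp(stream, rate, as.integer(n))
}

#' Advance positions by one Brownian step
#'
#' Adds an independent Normal(0, sqrt(2 D dt)) increment to every coordinate.
#'
#' @param p numeric vector of length 3 or an n x 3 matrix of positions (um).
#' @param D diffusion coefficient (um^2/min), non-negative.
#' @param dt time step (min), positive.
#' @param stream an [rng_stream()].
#' @return Object of the same shape as `p`.
#' @export
brownian_step <- function(p, D, dt, stream) {
  if (!is.numeric(D) || D < 0) stop("`D` must be non-negative", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  check_stream(stream)
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 3) else p
  out <- cpp_brownian_step(m, D, dt, stream)
  if (vec) drop(out) else out
}

#' Reflect points into a spherical shell
#'
#' Mirror reflection across the violated spherical boundary, applied
#' iteratively until the point lies in `r_inner <= |p - center| <= r_outer`.
#' Interior points are returned unchanged.
#'
#' @param p numeric vector of length 3 or an n x 3 matrix.
#' @param center centre of the shell.
#' @param r_inner,r_outer shell radii (um) with `0 <= r_inner < r_outer`.
#' @return Object of the same shape as `p`, inside the shell.
#' @export
reflect_in_shell <- function(p, center = c(0, 0, 0), r_inner = 0, r_outer) {
  if (!is.numeric(r_inner) || !is.numeric(r_outer) || r_inner < 0 ||
      r_inner >= r_outer)
    stop("need 0 <= r_inner < r_outer", call. = FALSE)
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 3) else p
  out <- cpp_reflect_shell(m, as.double(center), r_inner, r_outer)
  if (vec) drop(out) else out
}

#' Sample points uniformly on a sphere
#'
#' @param center centre of the sphere.
#' @param r radius (um), positive.
#' @param n number of points.
#' @param stream an [rng_stream()].
#' @return An n x 3 matrix of points at distance `r` from `center`.
#' @export
uniform_point_on_sphere <- function(center = c(0, 0, 0), r, n = 1L, stream) {
  if (!is.numeric(r) || r <= 0) stop("`r` must be positive", call. = FALSE)
  check_stream(stream)
  u <- cpp_runit(stream, as.integer(n))
  sweep(u * r, 2, as.double(center), "+")
}

#' Sample points uniformly in a spherical shell
#'
#' Volume-uniform placement between two concentric spheres; used for the EGF
#' introduction layer and for initial molecule positions.
#'
#' @inheritParams reflect_in_shell
#' @param n number of points.
#' @param stream an [rng_stream()].
#' @return An n x 3 matrix.
#' @export
uniform_point_in_shell <- function(center = c(0, 0, 0), r_inner = 0, r_outer,
                                   n = 1L, stream) {
  if (r_inner < 0 || r_inner >= r_outer)
    stop("need 0 <= r_inner < r_outer", call. = FALSE)
  check_stream(stream)
  sweep(cpp_sample_shell(stream, r_inner, r_outer, as.integer(n)), 2,
        as.double(center), "+")
}
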