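SPECIES <- c("ras", "raf", "erk", "tf")

#' Describe a cell's mutation profile
#'
#' K-Ras and B-Raf mutations downregulate the inactivation of the
#' corresponding activated proteins (their rate is multiplied by a factor in
#' (0, 1]); EGFR overexpression raises the number of receptor clusters.
#'
#' @param kras,braf logical flags for the mutations.
#' @param kras_multiplier,braf_multiplier inactivation-rate multipliers in
#'   (0, 1].
#' @param n_egfr number of EGFR clusters on the membrane (>= 1).
#' @return A list of class `mutation_profile`.
#' @export
mutation_profile <- function(kras = FALSE, braf = FALSE,
                             kras_multiplier = 0.01, braf_multiplier = 0.01,
                             n_egfr = 6L) {
  if (kras_multiplier <= 0 || kras_multiplier > 1 ||
      braf_multiplier <= 0 || braf_multiplier > 1)
    stop("mutation multipliers must be in (0, 1]", call. = FALSE)
  if (n_egfr < 1) stop("n_egfr must be at least 1", call. = FALSE)
  structure(list(kras = isTRUE(kras), braf = isTRUE(braf),
                 kras_multiplier = kras_multiplier,
                 braf_multiplier = braf_multiplier,
                 n_egfr = as.integer(n_egfr)),
            class = "mutation_profile")
}

#' Named mutation profiles used by the scenario runners
#'
#' @param name one of `"normal"`, `"kras"`, `"braf"`, `"kras_braf"`.
#' @param config an `egfr_config` supplying multipliers and receptor count.
#' @return A [mutation_profile()].
#' @export
named_profile <- function(name = c("normal", "kras", "braf", "kras_braf"),
                          config = sim_config()) {
  name <- match.arg(name)
  mutation_profile(kras = name %in% c("kras", "kras_braf"),
                   braf = name %in% c("braf", "kras_braf"),
                   kras_multiplier = config$kras_multiplier,
                   braf_multiplier = config$braf_multiplier,
                   n_egfr = config$n_egfr)
}

#' Mutation-adjusted inactivation rates
#'
#' @param profile a [mutation_profile()].
#' @param base_rates named numeric vector with elements `ras`, `raf`, `erk`,
#'   `tf` (1/min), all positive.
#' @return Named numeric vector of effective inactivation rates.
#' @export
apply_mutation <- function(profile, base_rates) {
  stopifnot(inherits(profile, "mutation_profile"))
  r <- base_rates[SPECIES]
  if (any(!is.finite(r)) || any(r <= 0))
    stop("base rates must be positive for ras, raf, erk, tf", call. = FALSE)
  if (profile$kras) r["ras"] <- r["ras"] * profile$kras_multiplier
  if (profile$braf) r["raf"] <- r["raf"] * profile$braf_multiplier
  r
}

base_rates <- function(config) {
  c(ras = config$k_inact_ras, raf = config$k_inact_raf,
    erk = config$k_inact_erk, tf = config$k_inact_tf)
}

#' Initialize the molecules of one cell
#'
#' All molecules start in the 'off' state: Ras, Raf and ERK uniformly in the
#' cytoplasm (the shell between nucleus and membrane), transcription factors
#' uniformly in the nucleus. Intracellular proteins never degrade, so these
#' per-species counts are invariants of the cell's lifetime.
#'
#' @param geometry list with `cell_radius` and `nucleus_radius` (um).
#' @param counts named integer vector `c(ras=, raf=, erk=, tf=)`; defaults
#'   are the model's 200/60/300/50.
#' @param stream an [rng_stream()].
#' @return An interior object: list with `species` (1=Ras, 2=Raf, 3=ERK,
#'   4=TF), `state` (0/1), `pos` (cell-local n x 3), `soff` (pending
#'   switch-off times).
#' @export
init_cell_molecules <- function(geometry,
                                counts = c(ras = 200L, raf = 60L,
                                           erk = 300L, tf = 50L),
                                stream) {
  if (geometry$nucleus_radius >= geometry$cell_radius)
    stop("nucleus must be strictly smaller than the cell", call. = FALSE)
  check_stream(stream)
  counts <- counts[SPECIES]
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be named non-negative integers for ras, raf, erk, tf",
         call. = FALSE)
  cpp_init_molecules(as.integer(counts), geometry$cell_radius,
                     geometry$nucleus_radius, stream)
}

#' Count the active transcription factors of an interior
#'
#' The number of active TFs in the nucleus decides the fate of the cell at
#' the end of its G1 phase.
#'
#' @param interior an interior object (see [init_cell_molecules()]).
#' @return Integer count of TF molecules in the 'on' state.
#' @export
count_active_tf <- function(interior) {
  sum(interior$state == 1L & interior$species == 4L)
}

count_active <- function(interior) {
  out <- integer(4)
  for (s in 1:4) out[s] <- sum(interior$state == 1L & interior$species == s)
  setNames(out, SPECIES)
}

#' Advance one cell interior by one Brownian-Dynamics step
#'
#' In order: every molecule diffuses and is reflected into its compartment;
#' bimolecular activations fire wherever reaction radii overlap (Ras by the
#' G-protein sphere of an active receptor, Raf by active Ras, ERK by active
#' Raf, TF by active ERK inside the nucleus), each newly activated molecule
#' drawing an exponential residence time at its mutation-adjusted
#' inactivation rate; molecules past their switch-off time return to 'off'.
#'
#' @param interior an interior object.
#' @param inner_spheres m x 3 matrix of active receptors' inner (G-protein)
#'   sphere centres in cell-local coordinates; may have zero rows.
#' @param rates named effective inactivation rates from [apply_mutation()].
#' @param geometry list with `cell_radius`, `nucleus_radius`.
#' @param dt time step (min).
#' @param clock current simulation time (min).
#' @param stream an [rng_stream()].
#' @param config an `egfr_config` supplying `d_protein`, `r_bd`,
#'   `r_receptor`, `use_grid`.
#' @return The updated interior object.
#' @export
step_interior <- function(interior, inner_spheres, rates, geometry, dt, clock,
                          stream, config = sim_config()) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  check_stream(stream)
  if (is.null(inner_spheres)) inner_spheres <- matrix(numeric(0), ncol = 3)
  if (is.null(dim(inner_spheres)))
    inner_spheres <- matrix(inner_spheres, ncol = 3)
  cpp_step_interior(interior, geometry$cell_radius, geometry$nucleus_radius,
                    inner_spheres, as.double(rates[SPECIES]),
                    config$d_protein, config$r_bd, config$r_receptor,
                    dt, clock, stream, isTRUE(config$use_grid))
}

#' Split a mother interior between two daughters
#'
#' Each daughter inherits exactly half of every species (a fair coin assigns
#' the odd molecule), with on/off states and pending switch-off times
#' preserved per molecule; coordinates are re-drawn uniformly in the
#' daughter's compartments to account for dilution at division.
#'
#' @param mother an interior object.
#' @param geometry daughter geometry (`cell_radius`, `nucleus_radius`).
#' @param stream an [rng_stream()].
#' @return List of two interior objects.
#' @export
halve_on_division <- function(mother, geometry, stream) {
  check_stream(stream)
  cpp_halve_interior(mother, geometry$cell_radius, geometry$nucleus_radius,
                     stream)
}
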