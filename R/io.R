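#' Write a tidy time-series table as CSV
#'
#' Fixed column order, header included, locale-independent numerics.
#'
#' @param records a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a time-series table
#'
#' @param path a CSV written by [write_timeseries()].
#' @return A data frame.
#' @export
read_timeseries <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a simulation snapshot as a CSV point cloud
#'
#' One row per living cell (kind `"cell"`: position, radius, phase, active-TF
#' count) and one per free EGF particle (kind `"egf"`), suitable for 3D
#' rendering.
#'
#' @param state an `egfr_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  cells <- do.call(rbind, lapply(state$cells, function(c) {
    data.frame(kind = "cell", id = c$id, x = c$pos[1], y = c$pos[2],
               z = c$pos[3], radius = c$radius, phase = c$phase,
               active_tf = count_active_tf(c$interior))
  }))
  egf <- NULL
  if (nrow(state$field$pos) > 0) {
    egf <- data.frame(kind = "egf", id = seq_len(nrow(state$field$pos)),
                      x = state$field$pos[, 1], y = state$field$pos[, 2],
                      z = state$field$pos[, 3], radius = NA, phase = NA,
                      active_tf = NA)
  }
  write.csv(rbind(cells, egf), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run bit-for-bit: the scenario
#' name, the full configuration, the seed, and the package version.
#'
#' @param scenario scenario name.
#' @param config an `egfr_config`.
#' @param seed integer seed.
#' @param extra optional named list of additional entries.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(scenario, config, seed, extra = list()) {
  structure(c(list(scenario = scenario, seed = seed,
                   package = "egfrsim",
                   version = as.character(packageVersion("egfrsim")),
                   config = unclass(config)), extra),
            class = "run_manifest")
}

#' Write a run manifest as YAML
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Deterministic miniature states for testing
#'
#' @param kind one of `"single-cell"` (one cell, one receptor, no field),
#'   `"two-cell-overlap"` (two cells at an overlapping centre distance),
#'   `"cell-free-field"` (no cells, a small stationary field), or
#'   `"mini-tumour"` (one cell in a small active field).
#' @param seed integer seed.
#' @return An `egfr_state`.
#' @export
make_fixture <- function(kind = c("single-cell", "two-cell-overlap",
                                  "cell-free-field", "mini-tumour"),
                         seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "single-cell") {
    cfg <- sim_config(field_enabled = FALSE, mechanics_enabled = FALSE,
                      fate_enabled = FALSE)
    state <- new_simulation(cfg, seed = seed)
    state$cells[[1]]$receptors <- list(anchor = matrix(c(0, 0, 1), ncol = 3),
                                       state = 1L, soff = 8)
    state
  } else if (kind == "two-cell-overlap") {
    cfg <- sim_config(field_enabled = FALSE, fate_enabled = FALSE,
                      n_ras = 2L, n_raf = 1L, n_erk = 1L, n_tf = 1L)
    state <- new_simulation(cfg, seed = seed, n_cells = 1L)
    stream <- rng_stream(seed, stream_id = 97L)
    second <- new_cell(cfg, id = 2L, pos = c(7.5, 0, 0), stream = stream)
    state$cells <- c(state$cells, list(second))
    state$next_id <- 3L
    state
  } else if (kind == "cell-free-field") {
    cfg <- sim_config(domain_radius = 30, introduction_rate = 2,
                      degradation_rate = 0.1, mechanics_enabled = FALSE,
                      fate_enabled = FALSE)
    new_simulation(cfg, seed = seed, n_cells = 0L)
  } else {
    cfg <- sim_config(domain_radius = 40, introduction_rate = 8,
                      degradation_rate = 0.1)
    new_simulation(cfg, seed = seed, n_cells = 1L)
  }
}
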