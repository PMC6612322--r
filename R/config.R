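#' Parameter catalogue with defaults, units and provenance
#'
#' Every tunable of the simulator, its default value, unit, and where the
#' default comes from: `"literature"` for values the model family states
#' directly (total of 610 intracellular molecules split 200/60/300/50, a
#' stationary cell-free EGF count of about 660, an 8 min mean receptor
#' residence time, a 24 h +/- 3 h cell cycle, time step 0.005 min),
#' `"calibrated"` for values fixed by reproducing stated behaviours (the
#' ~40 min transcription-factor transient after a single 8 min receptor
#' activation; a G1 checkpoint that separates stimulated from unstimulated
#' cells), and `"assumed"` for ordinary modelling choices.
#'
#' @return A data frame with columns `key`, `default`, `unit`, `provenance`,
#'   `description`.
#' @export
config_catalogue <- function() {
  row <- function(key, default, unit, prov, desc) {
    data.frame(key = key, default = I(list(default)), unit = unit,
               provenance = prov, description = desc,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    row("domain_radius", 120, "um", "literature",
        "radius of the spherical extracellular domain"),
    row("shell_thickness", 5, "um", "assumed",
        "thickness of the outer EGF introduction layer"),
    row("d_egf", 25, "um^2/min", "calibrated",
        "EGF diffusion coefficient in the extracellular matrix"),
    row("introduction_rate", 22, "1/min", "calibrated",
        "EGF introduction rate; ratio to degradation_rate gives ~660"),
    row("degradation_rate", 1 / 30, "1/min", "calibrated",
        "EGF degradation rate (mean lifetime 30 min)"),
    row("r_egf", 0.05, "um", "calibrated", "EGF reaction radius"),
    row("r_receptor", 0.5, "um", "assumed",
        "radius of the two clamped receptor spheres"),
    row("k_off_receptor", 1 / 8, "1/min", "literature",
        "receptor inactivation rate (mean residence time 8 min)"),
    row("egf_rerelease", FALSE, "flag", "assumed",
        "re-release bound EGF on receptor switch-off instead of consuming"),
    row("cell_radius", 5, "um", "assumed", "cell radius at birth"),
    row("nucleus_radius", 2.5, "um", "assumed",
        "radius of the incompressible nucleus"),
    row("n_ras", 200L, "molecules", "literature", "Ras copy number per cell"),
    row("n_raf", 60L, "molecules", "literature", "Raf copy number per cell"),
    row("n_erk", 300L, "molecules", "literature", "ERK copy number per cell"),
    row("n_tf", 50L, "molecules", "literature",
        "transcription factor copy number per cell"),
    row("d_protein", 0.5, "um^2/min", "calibrated",
        "intracellular protein diffusion coefficient"),
    row("r_bd", 0.1, "um", "calibrated",
        "reaction radius of intracellular proteins"),
    row("k_inact_ras", 0.08, "1/min", "calibrated",
        "Ras spontaneous inactivation rate"),
    row("k_inact_raf", 0.08, "1/min", "calibrated",
        "Raf spontaneous inactivation rate"),
    row("k_inact_erk", 0.08, "1/min", "calibrated",
        "ERK spontaneous inactivation rate"),
    row("k_inact_tf", 0.05, "1/min", "calibrated",
        "transcription factor inactivation rate"),
    row("kras_multiplier", 0.01, "fraction", "assumed",
        "K-Ras mutation: factor applied to the Ras inactivation rate"),
    row("braf_multiplier", 0.01, "fraction", "assumed",
        "B-Raf mutation: factor applied to the Raf inactivation rate"),
    row("n_egfr", 6L, "receptors", "literature",
        "EGFR clusters per cell (6/12/24 in the overexpression scenarios)"),
    row("dt", 0.005, "min", "literature", "operator-splitting time step"),
    row("mass", 1, "arbitrary", "assumed", "cell mass in the equation of motion"),
    row("friction", 10, "1/min", "assumed",
        "friction factor from contact with the surrounding medium"),
    row("k_repulsion", 100, "force", "calibrated",
        "scale of the pairwise repulsive force"),
    row("g1_duration", 660, "min", "assumed",
        "G1 phase duration (11 h of the 24 h cycle)"),
    row("cycle_min", 1260, "min", "literature",
        "shortest cell cycle (24 h - 3 h)"),
    row("cycle_max", 1620, "min", "literature",
        "longest cell cycle (24 h + 3 h)"),
    row("n_tf_star", 12, "molecules", "calibrated",
        "active-TF threshold at the G1 checkpoint (strictly exceeded)"),
    row("use_grid", TRUE, "flag", "assumed",
        "use spatial binning for overlap searches"),
    row("field_enabled", TRUE, "flag", "assumed",
        "propagate the extracellular field"),
    row("mechanics_enabled", TRUE, "flag", "assumed",
        "integrate cell motion"),
    row("fate_enabled", TRUE, "flag", "assumed",
        "apply cycle/fate rules (checkpoint, growth, division)"),
    row("keep_corpses", FALSE, "flag", "assumed",
        "keep apoptotic cells as inert spheres instead of removing them"),
    row("operator_order", "fim", "string", "literature",
        "operator-splitting order: field, interiors, mechanics")
  ))
}

config_defaults <- function() {
  cat <- config_catalogue()
  setNames(cat$default, cat$key)
}

#' Build a validated simulation configuration
#'
#' @param ... named overrides of the defaults in [config_catalogue()].
#' @return A named list of class `egfr_config`.
#' @examples
#' cfg <- sim_config(n_egfr = 12L)
#' cfg$n_egfr
#' @export
sim_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  defaults <- config_defaults()
  dup <- unique(names(over)[duplicated(names(over))])
  if (length(dup))
    stop("duplicated configuration key(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "egfr_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg,
                                         call. = FALSE)
  pos <- c("domain_radius", "shell_thickness", "d_egf", "degradation_rate",
           "r_egf", "r_receptor", "k_off_receptor", "cell_radius",
           "nucleus_radius", "d_protein", "r_bd", "k_inact_ras",
           "k_inact_raf", "k_inact_erk", "k_inact_tf", "dt", "mass",
           "friction", "k_repulsion", "g1_duration", "cycle_min",
           "cycle_max")
  for (k in pos)
    chk(is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1 && is.finite(cfg[[k]]) &&
          cfg[[k]] > 0, paste0(k, " must be a positive number"))
  chk(cfg$introduction_rate >= 0, "introduction_rate must be >= 0")
  chk(cfg$nucleus_radius < cfg$cell_radius,
      "nucleus_radius must be smaller than cell_radius")
  chk(cfg$shell_thickness <= cfg$domain_radius,
      "shell_thickness must not exceed domain_radius")
  for (k in c("kras_multiplier", "braf_multiplier"))
    chk(cfg[[k]] > 0 && cfg[[k]] <= 1, paste0(k, " must be in (0, 1]"))
  for (k in c("n_ras", "n_raf", "n_erk", "n_tf"))
    chk(cfg[[k]] >= 0 && cfg[[k]] == as.integer(cfg[[k]]),
        paste0(k, " must be a non-negative integer"))
  chk(cfg$n_egfr >= 1, "n_egfr must be at least 1")
  chk(cfg$cycle_min <= cfg$cycle_max, "cycle_min must not exceed cycle_max")
  chk(cfg$g1_duration < cfg$cycle_min,
      "g1_duration must be shorter than the shortest cycle")
  chk(is.character(cfg$operator_order) && nchar(cfg$operator_order) == 3 &&
        setequal(strsplit(cfg$operator_order, "")[[1]], c("f", "i", "m")),
      "operator_order must be a permutation of \"fim\"")
  invisible(cfg)
}

#' Load a configuration from a flat YAML file
#'
#' The file holds a flat mapping from keys of [config_catalogue()] to values.
#' Unknown keys are an error so that typos cannot silently fall back to
#' defaults; an empty file yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return A validated `egfr_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a flat YAML mapping",
                          call. = FALSE)
  do.call(sim_config, raw)
}

#' @export
print.egfr_config <- function(x, ...) {
  cat("<egfr_config> ", length(x), " parameters\n", sep = "")
  cat(sprintf("  domain %g um, dt %g min, %d EGFR/cell, N_TF* %g\n",
              x$domain_radius, x$dt, x$n_egfr, x$n_tf_star))
  invisible(x)
}
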