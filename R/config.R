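# Run configuration: a structured YAML file whose blocks mirror the model's
# parameter tables. Every block is optional; omitted keys take the model
# defaults, unknown keys are rejected by name.

#' Default run configuration
#'
#' The resolved defaults of every configuration block: geometry, scaffold
#' material, potentials (kap-FG, FG-FG, repulsion), integrator, cargo and
#' output. Potential parameters default to the model's standard coarse-grained
#' parameter set (kap-FG 2 kT / 1.5 nm, FG-FG 1.5 kT / 1 nm, repulsion
#' 100 kT / 1 nm / 1.35 nm cutoff, persistence 0.43 nm, viscosity 5 cP,
#' protein density 1.35 g/cm^3).
#'
#' @return nested named list of defaults.
#' @export
default_run_config <- function() {
  geo <- unclass(geometry_config())
  geo$transport_span <- NULL
  geo$simulation_dimensionality <- NULL
  geo$fg_region_weights <- unname(geo$fg_region_weights) # YAML-stable
  list(
    geometry = geo,
    material = scaffold_material(),
    potentials = list(
      kap_fg = list(epsilon = 2, xi = 1.5, cutoff = 10),
      fg_fg = list(epsilon = 1.5, xi = 1, cutoff = 10),
      repulsion = list(epsilon_rep = 100, sigma = 1, cutoff = 1.35)),
    integrator = list(dt = 1, n_steps = 2e7, f_max = 0.99,
                      sample_every = 100, skin = 2, contact_radius = 3,
                      equil_steps = 1e6, temperature_K = 310,
                      viscosity_cP = 5),
    cargo = list(diameter = 15, n_spots = 8),
    seed = 1,
    output = list(dir = "npcbd-out")
  )
}

.merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    abort(sprintf("config block '%s' must be a mapping",
                  paste(path, collapse = "/")),
          class = "npcbd_config_error")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    full <- vapply(unknown, function(k) paste(c(path, k), collapse = "/"),
                   character(1))
    abort(sprintf("unknown config key%s: %s",
                  if (length(unknown) > 1) "s" else "",
                  paste(full, collapse = ", ")),
          class = "npcbd_config_error")
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]])) {
      .merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load and resolve a run configuration
#'
#' Reads a YAML configuration, merges it over [default_run_config()], and
#' rejects unknown keys by name. An empty file resolves to the full default
#' parameter set.
#'
#' @param path YAML file path.
#' @return the resolved configuration (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "npcbd_io_error")
  }
  user <- yaml::read_yaml(path)
  resolve_config(user)
}

#' Resolve a configuration list against the defaults
#'
#' @param user nested list of overrides (possibly `NULL`).
#' @return the resolved configuration (class `run_config`).
#' @export
resolve_config <- function(user = NULL) {
  cfg <- .merge_config(default_run_config(), user)
  structure(cfg, class = "run_config")
}

#' Save a resolved configuration as YAML
#'
#' @param config a `run_config` (or compatible list).
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Instantiate model objects from a resolved configuration
#'
#' @param config a `run_config`.
#' @return a list with `structure` builders' inputs realized: `geometry`
#'   ([geometry_config()]), `material`, `rules` ([interaction_rules()]),
#'   `cargo` ([make_cargo()]) and `integrator` ([integrator_config()]).
#' @export
config_objects <- function(config) {
  stopifnot(inherits(config, "run_config"))
  g <- config$geometry
  geometry <- do.call(geometry_config, g)
  p <- config$potentials
  rules <- interaction_rules(
    fg_fg = hydrophobic_rule(p$fg_fg$epsilon, p$fg_fg$xi, p$fg_fg$cutoff),
    kap_fg = hydrophobic_rule(p$kap_fg$epsilon, p$kap_fg$xi,
                              p$kap_fg$cutoff),
    repulsion = repulsive_rule(p$repulsion$epsilon_rep, p$repulsion$sigma,
                               p$repulsion$cutoff))
  it <- config$integrator
  integrator <- integrator_config(
    dt = it$dt, n_steps = it$n_steps, seed = config$seed,
    f_max = it$f_max, sample_every = it$sample_every, skin = it$skin,
    contact_radius = it$contact_radius, temperature_K = it$temperature_K,
    viscosity_cP = it$viscosity_cP)
  cargo <- make_cargo(config$cargo$diameter, config$cargo$n_spots,
                      kap_fg = rules$kap_fg,
                      viscosity_cP = it$viscosity_cP,
                      temperature_K = it$temperature_K)
  list(geometry = geometry,
       material = do.call(scaffold_material, config$material),
       rules = rules, cargo = cargo, integrator = integrator,
       equil_steps = it$equil_steps)
}
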