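# R-side interface to the C++ Brownian-dynamics engine: packing an
# `npc_structure` (+ cargo) into flat arrays, force evaluation, and the
# simulation drivers.

.group_code <- c(pom_anchor = 0L, scaffold = 1L, fg_central = 2L,
                 fg_peripheral = 3L, cargo = 4L)

#' Integrator configuration
#'
#' The explicit overdamped Langevin scheme advances every mobile bead by
#' x <- x + F D dt + dx_B, with dx_B Gaussian of variance 2 D dt per
#' component, then applies the rejection rules (finite WLC extensibility,
#' rigid envelope).
#'
#' @param dt time step in reduced units (1 = 0.1 ns).
#' @param n_steps maximum number of steps.
#' @param seed integer seed of the run's random stream.
#' @param f_max rejection threshold: a move is rejected when it would take a
#'   WLC segment to an extension of `f_max * L_s` or beyond.
#' @param sample_every trajectory sampling stride (steps).
#' @param skin neighbor-list skin distance (nm); lists are rebuilt whenever
#'   accumulated displacements could let an unlisted pair enter a cutoff.
#' @param contact_radius spot-motif distance defining a hydrophobic
#'   "bond" for the lifetime/occupancy bookkeeping (nm). The default 3 nm
#'   is twice the kap-FG characteristic length - the width of the
#'   interaction well, deliberately much smaller than the 10 nm force
#'   cutoff (which would register near-permanent contacts).
#' @param noise logical; `FALSE` disables the Brownian displacement
#'   (deterministic drift, used in tests).
#' @param record_contact_log keep the full per-step (spot, motif) contact
#'   log (memory-heavy; only for short runs).
#' @param stop_on_end stop as soon as the cargo is completely loaded into
#'   the basket (RanGTP release is instantaneous by assumption).
#' @param temperature_K,viscosity_cP conditions, for reference in outputs.
#' @return an `integrator_config` list.
#' @export
integrator_config <- function(dt = 1, n_steps = 1e5, seed = 1, f_max = 0.99,
                              sample_every = 100, skin = 2,
                              contact_radius = 3, noise = TRUE,
                              record_contact_log = FALSE, stop_on_end = TRUE,
                              temperature_K = 310, viscosity_cP = 5) {
  stopifnot(dt > 0, f_max > 0, f_max < 1, n_steps >= 0, sample_every >= 1)
  structure(as.list(environment()), class = "integrator_config")
}

#' Gaussian Brownian displacement
#'
#' Each Cartesian component is drawn i.i.d. from N(0, 2 D dt) (reduced
#' units). Uses R's RNG, so `set.seed()` makes draws reproducible.
#'
#' @param D_um2_s diffusion coefficient in um^2/s.
#' @param dt time step in reduced units.
#' @param n number of displacement vectors.
#' @return an `n` x 2 matrix of displacements in nm.
#' @export
brownian_displacement <- function(D_um2_s, dt = 1, n = 1) {
  if (any(D_um2_s <= 0)) {
    abort("diffusion coefficient must be positive",
          class = "npcbd_domain_error")
  }
  sd <- sqrt(2 * diffusion_to_reduced(D_um2_s) * dt)
  matrix(rnorm(2 * n, 0, sd), ncol = 2)
}

#' Single overdamped Langevin step (reference implementation)
#'
#' The R-level form of the update used by the engine, handy for
#' deterministic unit checks: immobile beads stay put, mobile beads drift
#' by F D dt plus (optionally) a Brownian displacement.
#'
#' @param positions N x 2 matrix (nm).
#' @param forces N x 2 matrix (kT/nm).
#' @param diffusion length-N diffusion coefficients (um^2/s).
#' @param mobile logical length-N.
#' @param dt time step (reduced units).
#' @param noise draw Brownian displacements (via R's RNG)?
#' @return the proposed N x 2 positions.
#' @export
bd_step <- function(positions, forces, diffusion, mobile, dt = 1,
                    noise = FALSE) {
  Dred <- diffusion_to_reduced(diffusion)
  prop <- positions + forces * Dred * dt
  if (noise) {
    prop <- prop + matrix(rnorm(2 * nrow(positions), 0,
                                sqrt(2 * Dred * dt)), ncol = 2)
  }
  prop[!mobile, ] <- positions[!mobile, ]
  prop
}

# ---------------------------------------------------------------------------

.pack_system <- function(structure, cargo = NULL, cargo_position = NULL,
                         rules = interaction_rules(), wall_on = TRUE,
                         confine = NULL) {
  b <- structure$beads
  pos <- cbind(b$x, b$y)
  group <- unname(.group_code[b$group])
  mobile <- b$mobile
  Dred <- diffusion_to_reduced(b$diffusion)
  has_cargo <- !is.null(cargo)
  if (has_cargo) {
    stopifnot(inherits(cargo, "cargo"), length(cargo_position) == 2)
    pos <- rbind(pos, cargo_position)
    group <- c(group, .group_code[["cargo"]])
    mobile <- c(mobile, TRUE)
    Dred <- c(Dred, diffusion_to_reduced(cargo$diffusion))
  }
  N <- nrow(pos)
  bonds <- as.matrix(structure$bonds[, c("i", "j", "k_s", "r0")])
  angles <- as.matrix(structure$angles[, c("i", "j", "k", "k_theta",
                                           "theta0")])
  wlc <- as.matrix(structure$wlc[, c("i", "j", "L_s", "l_p")])
  excl <- rbind(as.matrix(structure$bonds[, c("i", "j")]),
                as.matrix(structure$wlc[, c("i", "j")]))
  storage.mode(excl) <- "integer"
  w <- structure$wall
  wall <- list(enabled = isTRUE(wall_on), y_lo = w$y_lo, y_hi = w$y_hi,
               r_waist = w$r_waist, r_entr = w$r_entr, margin = w$margin,
               box = !is.null(confine))
  if (wall$box) {
    wall$box_x <- confine$x
    wall$box_ytop <- confine$ytop
    wall$box_ybot <- confine$ybot
  }
  cargo_l <- list(has = has_cargo)
  if (has_cargo) {
    cargo_l$idx <- N
    cargo_l$radius <- cargo$radius
    cargo_l$spots <- cargo$spot_offsets
    cargo_l$eps <- cargo$kap_fg$epsilon
    cargo_l$xi <- cargo$kap_fg$xi
    cargo_l$cutoff <- cargo$kap_fg$cutoff
  }
  fil_chains <- structure$chains$chain_id[structure$chains$region ==
                                            "filament"]
  filament_fg <- rep(FALSE, N)
  fil_ids <- unlist(structure$chains$bead_ids[
    structure$chains$chain_id %in% fil_chains])
  filament_fg[fil_ids] <- TRUE
  list(pos = pos, group = as.integer(group), mobile = mobile, D = Dred,
       bonds = bonds, angles = angles, wlc = wlc, excl = excl,
       rules = list(eps_ff = rules$fg_fg$epsilon, xi_ff = rules$fg_fg$xi,
                    cut_h = rules$fg_fg$cutoff,
                    eps_rep = rules$repulsion$epsilon_rep,
                    sigma = rules$repulsion$sigma,
                    cut_rep = rules$repulsion$cutoff),
       wall = wall, cargo = cargo_l, filament_fg = filament_fg)
}

#' Total forces and energy decomposition
#'
#' Sums the bonded terms (harmonic bonds and pom springs, cosine bending,
#' WLC segments) and the nonbonded terms (FG-FG hydrophobic attraction
#' among central FG beads, kap-FG attraction on the cargo's binding spots,
#' soft repulsion between all nonbonded pairs) for the current coordinates.
#' Pairwise antisymmetry holds exactly, so internal forces sum to the zero
#' vector over all beads including wall anchors.
#'
#' @param structure an `npc_structure`.
#' @param cargo optional [make_cargo()] object.
#' @param cargo_position cargo center (x, y), required with `cargo`.
#' @param positions optional N x 2 coordinate matrix overriding the stored
#'   bead coordinates (beads only, cargo excluded).
#' @param rules an [interaction_rules()] set.
#' @param neighbor_list use the cell/neighbor list (as the simulation
#'   does) instead of the exact all-pairs sum.
#' @return a list with `forces` (tibble: bead, fx, fy) and `energy`
#'   (named vector of the six contributions, kT).
#' @export
total_forces <- function(structure, cargo = NULL, cargo_position = NULL,
                         positions = NULL, rules = interaction_rules(),
                         neighbor_list = FALSE) {
  pk <- .pack_system(structure, cargo, cargo_position, rules,
                     wall_on = FALSE)
  if (!is.null(positions)) {
    stopifnot(nrow(positions) == nrow(structure$beads))
    pk$pos[seq_len(nrow(positions)), ] <- positions
  }
  out <- cpp_total_forces(pk$pos, pk$group, pk$mobile, pk$D, pk$bonds,
                          pk$angles, pk$wlc, pk$excl, pk$rules, pk$wall,
                          pk$cargo, neighbor_list)
  list(forces = tibble(bead = seq_len(nrow(pk$pos)),
                       fx = out$forces[, 1], fy = out$forces[, 2]),
       energy = out$energy, max_wlc_ratio = out$max_wlc_ratio)
}

.run_engine <- function(pk, config, detect_events, track_bead = -1L) {
  control <- list(
    dt = config$dt, f_max = config$f_max, n_steps = config$n_steps,
    sample_every = as.integer(config$sample_every), noise = config$noise,
    skin = config$skin, seed = as.double(config$seed),
    contact_radius = config$contact_radius,
    record_contact_log = config$record_contact_log,
    detect_events = detect_events, stop_on_end = config$stop_on_end,
    y_basket_top = pk$planes$basket_top, y_basket_bottom = pk$planes$exit,
    filament_fg = pk$filament_fg, track_bead = as.integer(track_bead))
  cpp_run(pk$pos, pk$group, pk$mobile, pk$D, pk$bonds, pk$angles, pk$wlc,
          pk$excl, pk$rules, pk$wall, pk$cargo, control)
}

#' Run a Brownian-dynamics simulation
#'
#' The basic driver: force evaluation, Langevin step, rejection, observer
#' bookkeeping, until the step budget is exhausted or (with an active event
#' detector) the cargo is completely loaded into the basket. Fully
#' reproducible from `(config, seed)`.
#'
#' @param structure an `npc_structure`.
#' @param cargo optional [make_cargo()] cargo-complex.
#' @param cargo_position cargo start position; default
#'   [place_cargo_at_entry()].
#' @param config an [integrator_config()].
#' @param rules an [interaction_rules()] set.
#' @param wall_on keep the rigid nuclear-envelope slab active.
#' @param confine optional reflecting confinement
#'   `list(x =, ytop =, ybot =)` bounding the open compartments (used to
#'   bound the cytoplasmic search volume, mirroring the near-entry start).
#' @param detect detect transport events (needs a cargo).
#' @param track_bead bead id whose trajectory is sampled when there is no
#'   cargo (default: the cargo when present, else bead 1).
#' @return a `transport_record`.
#' @export
run_simulation <- function(structure, cargo = NULL, cargo_position = NULL,
                           config = integrator_config(),
                           rules = interaction_rules(), wall_on = TRUE,
                           confine = NULL, detect = !is.null(cargo),
                           track_bead = 1L) {
  if (!is.null(cargo) && is.null(cargo_position)) {
    cargo_position <- place_cargo_at_entry(structure, cargo)
  }
  pk <- .pack_system(structure, cargo, cargo_position, rules, wall_on,
                     confine)
  pk$planes <- structure$planes
  out <- .run_engine(pk, config, detect,
                     track_bead = if (is.null(cargo)) track_bead else -1L)
  .wrap_record(out, structure, cargo, config)
}

.wrap_record <- function(out, structure, cargo, config) {
  dt <- config$dt
  track <- as_tibble(out$track)
  track$time_ms <- steps_to_ms(track$step, dt)
  track$r <- abs(track$x)
  episodes <- as_tibble(out$episodes)
  if (nrow(episodes) > 0) {
    episodes$spot <- as.integer(episodes$spot) + 1L
    episodes$motif <- as.integer(episodes$motif) + 1L
    episodes$lifetime_ns <- (episodes$end - episodes$start + 1) * dt * 0.1
  } else {
    episodes$lifetime_ns <- double(0)
  }
  contact_log <- as_tibble(out$contact_log)
  if (nrow(contact_log) > 0) {
    contact_log$spot <- as.integer(contact_log$spot) + 1L
    contact_log$motif <- as.integer(contact_log$motif) + 1L
  }
  t_start <- if (out$t_start >= 0) out$t_start else NA_real_
  t_end <- if (out$t_end >= 0) out$t_end else NA_real_
  completed <- !is.na(t_end)
  fpt_ms <- if (completed) {
    steps_to_ms(t_end - ifelse(is.na(t_start), 0, t_start), dt)
  } else NA_real_
  structure(list(
    track = track, episodes = episodes, contact_log = contact_log,
    events = list(
      t_start_step = t_start, t_end_step = t_end,
      t_start_ms = steps_to_ms(t_start, dt),
      t_end_ms = steps_to_ms(t_end, dt), fpt_ms = fpt_ms,
      outcome = if (completed) "completed" else "timed_out"),
    counters = list(
      steps_run = out$steps_run,
      occupancy_mean = if (out$engaged_steps > 0) {
        out$occupancy_sum / out$engaged_steps
      } else NA_real_,
      engaged_steps = out$engaged_steps, min_y = out$min_y,
      max_wlc_ratio = out$max_wlc_ratio,
      n_rejected_wlc = out$n_rejected_wlc,
      n_rejected_wall = out$n_rejected_wall),
    positions = out$positions, planes = structure$planes,
    cargo = cargo, dt = dt, seed = config$seed
  ), class = "transport_record")
}

#' @export
print.transport_record <- function(x, ...) {
  cat(sprintf("<transport_record> %s after %.3g ms (%g steps)\n",
              x$events$outcome, steps_to_ms(x$counters$steps_run, x$dt),
              x$counters$steps_run))
  if (!is.na(x$events$fpt_ms)) {
    cat(sprintf("  first-passage time: %.4g ms (start %.4g ms, end %.4g ms)\n",
                x$events$fpt_ms, x$events$t_start_ms, x$events$t_end_ms))
  }
  if (!is.na(x$counters$occupancy_mean)) {
    cat(sprintf("  mean engaged binding spots: %.2f over %g engaged steps\n",
                x$counters$occupancy_mean, x$counters$engaged_steps))
  }
  invisible(x)
}

#' Re-derive transport events from a recorded trajectory
#'
#' Offline event detection on a cargo track: the end of transport is the
#' first sampled step at which the whole cargo sphere lies inside the basket
#' region (below the nuclear-ring plane, above the distal ring); the start
#' is the first hydrophobically engaged sample (or the engine-recorded
#' first filament contact when available).
#'
#' @param record a `transport_record`.
#' @return the record with its `events` entry recomputed from the track.
#' @export
detect_events <- function(record) {
  stopifnot(inherits(record, "transport_record"))
  tr <- record$track
  R <- if (!is.null(record$cargo)) record$cargo$radius else 0
  inside <- tr$y + R <= record$planes$basket_top &
    tr$y - R >= record$planes$exit
  t_end <- if (any(inside)) tr$step[which(inside)[1]] else NA_real_
  engaged <- tr$engaged_spots > 0
  t_start <- record$events$t_start_step
  if (is.na(t_start) && any(engaged)) t_start <- tr$step[which(engaged)[1]]
  record$events$t_end_step <- t_end
  record$events$t_end_ms <- steps_to_ms(t_end, record$dt)
  record$events$t_start_step <- t_start
  record$events$t_start_ms <- steps_to_ms(t_start, record$dt)
  record$events$outcome <- if (!is.na(t_end)) "completed" else "timed_out"
  record$events$fpt_ms <- if (!is.na(t_end)) {
    steps_to_ms(t_end - ifelse(is.na(t_start), 0, t_start), record$dt)
  } else NA_real_
  record
}

#' Run one import: equilibrate, place cargo, simulate to basket loading
#'
#' Relaxes the FG layer (without cargo), places the cargo-complex at the
#' cytoplasmic entry, and integrates until complete basket loading or the
#' step budget.
#'
#' @inheritParams run_simulation
#' @param seed integer; seeds both the equilibration and transport streams.
#' @param equil_steps FG-layer relaxation steps before the cargo appears
#'   (default 1e6 = 0.1 ms).
#' @param standoff initial clearance above the filament tips (nm).
#' @param cargo_position optional explicit start position overriding
#'   [place_cargo_at_entry()] (e.g. at the channel mouth for shortened
#'   surrogate runs).
#' @return a `transport_record`.
#' @export
run_transport <- function(structure, cargo, seed = 1,
                          config = integrator_config(seed = seed),
                          rules = interaction_rules(), equil_steps = 1e6,
                          standoff = cargo$diameter, confine = NULL,
                          cargo_position = NULL) {
  eq_cfg <- config
  eq_cfg$n_steps <- equil_steps
  eq_cfg$seed <- seed
  eq_cfg$sample_every <- max(1e4, eq_cfg$sample_every)
  eq <- run_simulation(structure, cargo = NULL, config = eq_cfg,
                       rules = rules, confine = confine, detect = FALSE)
  relaxed <- structure
  relaxed$beads$x <- eq$positions[, 1]
  relaxed$beads$y <- eq$positions[, 2]
  pos0 <- cargo_position %||%
    place_cargo_at_entry(relaxed, cargo, standoff = standoff)
  run_cfg <- config
  run_cfg$seed <- seed + 1
  if (is.null(confine)) {
    confine <- list(x = structure$wall$r_entr + 30,
                    ytop = pos0[2] + cargo$radius + 30,
                    ybot = structure$planes$exit - 5)
  }
  run_simulation(relaxed, cargo, cargo_position = pos0, config = run_cfg,
                 rules = rules, confine = confine, detect = TRUE)
}

#' Run a batch of independent imports
#'
#' Independent seeded runs of [run_transport()]; per-run faults are caught
#' and recorded, not fatal to the batch.
#'
#' @inheritParams run_transport
#' @param n_runs number of independent runs.
#' @param base_seed run i uses seed `base_seed + 10 * (i - 1)`.
#' @return a list with `records` (per-run `transport_record` or condition),
#'   `fpt` (an [fpt_sample()] of completed runs) and `outcomes` (tibble).
#' @export
run_batch <- function(structure, cargo, n_runs, base_seed = 1,
                      config = integrator_config(), rules = interaction_rules(),
                      equil_steps = 1e6, confine = NULL,
                      cargo_position = NULL) {
  stopifnot(n_runs >= 1)
  seeds <- base_seed + 10 * (seq_len(n_runs) - 1)
  records <- map(seeds, function(s) {
    tryCatch(
      run_transport(structure, cargo, seed = s, config = config,
                    rules = rules, equil_steps = equil_steps,
                    confine = confine, cargo_position = cargo_position),
      error = function(e) e)
  })
  ok <- map_dbl(records, function(r) {
    if (inherits(r, "transport_record")) r$events$fpt_ms else NA_real_
  })
  outcomes <- tibble(
    run = seq_len(n_runs), seed = seeds,
    outcome = map_chr(records, function(r) {
      if (inherits(r, "transport_record")) r$events$outcome else "fault"
    }),
    fpt_ms = ok)
  list(records = records, fpt = fpt_sample(ok[!is.na(ok)]),
       outcomes = outcomes)
}
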