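# Building the discretized two-spoke NPC in a 2D cross-sectional plane.
# The pore axis is y (cytoplasm up, nucleus down): cytoplasmic ring plane at
# y = 0, central channel down to y = -channel_length, nuclear basket rods
# meeting the distal ring at y = -(channel_length + basket_length),
# cytoplasmic filaments rising to y = +filament_length. The nuclear envelope
# is a rigid slab spanning the channel's axial extent on both sides of the
# hourglass wall profile; it exerts no force but rejects any move into it.

#' Geometry configuration for the NPC model
#'
#' Dimensions approximate the cryo-EM picture of the *Xenopus* oocyte NPC:
#' a ~50 nm wide hourglass channel, ~35 nm cytoplasmic filaments and a
#' basket sized so the cytoplasmic-entry-to-basket-exit transport span is
#' exactly 160 nm. Two opposing spokes lie in the simulated cross-sectional
#' plane; the full pore has eight, so FG counts scale by 8/2 when compared
#' with per-NPC measurements.
#'
#' @param channel_min_diameter waist diameter of the hourglass channel (nm).
#' @param channel_entrance_diameter channel diameter at both rings (nm).
#' @param channel_length axial length of the central channel (nm).
#' @param filament_length length of the cytoplasmic filaments (nm).
#' @param basket_length axial depth of the nuclear basket (nm).
#' @param distal_ring_diameter diameter of the basket's distal ring (nm).
#' @param scaffold_bead_spacing target bead spacing for the elastic
#'   scaffold discretization (nm).
#' @param n_spokes number of spokes in the cross-sectional plane (2).
#' @param fg_total_motifs total FG-motif beads over all chains (720).
#' @param fg_central_contour contour length of central-channel FG-repeat
#'   domains (nm).
#' @param fg_peripheral_contour contour length of peripheral (filament and
#'   basket) FG-repeat domains (nm).
#' @param fg_segment_length contour length of one discrete-WLC segment (nm);
#'   must be at least ten persistence lengths.
#' @param fg_region_weights relative weights of the motif budget allocated
#'   to the filament, channel and basket regions (named or in that order).
#'   The default splits the 720 motifs evenly between the three regions.
#' @param persistence_length WLC persistence length of FG domains (nm).
#' @param scaffold_bead_radius hydrodynamic/geometric radius of scaffold
#'   beads (nm).
#' @param fg_bead_radius radius of FG-motif beads (nm).
#' @param pom_spring_length rest length of the pom anchor springs (nm).
#' @param wall_margin clearance between the scaffold wall line and the
#'   rigid nuclear-envelope slab (nm).
#' @return a validated `geometry_config` object. `transport_span` is the
#'   derived cytoplasmic-entry to basket-exit distance.
#' @export
geometry_config <- function(channel_min_diameter = 50,
                            channel_entrance_diameter = 70,
                            channel_length = 50,
                            filament_length = 35,
                            basket_length = 75,
                            distal_ring_diameter = 40,
                            scaffold_bead_spacing = 10,
                            n_spokes = 2,
                            fg_total_motifs = 720,
                            fg_central_contour = 50,
                            fg_peripheral_contour = 200,
                            fg_segment_length = 10,
                            fg_region_weights = c(filament = 1, channel = 1,
                                                  basket = 1),
                            persistence_length = 0.43,
                            scaffold_bead_radius = 3,
                            fg_bead_radius = 0.9,
                            pom_spring_length = 6,
                            wall_margin = 2) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(channel_min_diameter > 0, channel_length > 0,
              filament_length > 0, basket_length > 0,
              distal_ring_diameter > 0, fg_total_motifs > 0,
              fg_central_contour > 0, fg_peripheral_contour > 0,
              fg_segment_length > 0, persistence_length > 0)
  })
  if (cfg$n_spokes != 2) {
    abort("the cross-sectional plane holds exactly two opposing spokes",
          class = "npcbd_config_error")
  }
  if (cfg$channel_entrance_diameter < cfg$channel_min_diameter) {
    abort("entrance diameter must be at least the waist diameter",
          class = "npcbd_config_error")
  }
  if (cfg$fg_segment_length < 10 * cfg$persistence_length) {
    abort(paste0("fg_segment_length must be >= 10 persistence lengths ",
                 "(discrete-WLC validity)"), class = "npcbd_config_error")
  }
  smallest <- min(cfg$channel_length, cfg$filament_length, cfg$basket_length)
  if (cfg$scaffold_bead_spacing > smallest) {
    abort(sprintf(
      "scaffold bead spacing (%g nm) exceeds the smallest subunit (%g nm)",
      cfg$scaffold_bead_spacing, smallest), class = "npcbd_config_error")
  }
  if (length(cfg$fg_region_weights) != 3 || any(cfg$fg_region_weights <= 0)) {
    abort("fg_region_weights must be three positive weights",
          class = "npcbd_config_error")
  }
  cfg$simulation_dimensionality <- 2
  cfg$transport_span <- cfg$filament_length + cfg$channel_length +
    cfg$basket_length
  structure(cfg, class = "geometry_config")
}

#' Scaffold material parameters
#'
#' @param E_young_kPa Young's modulus of the NPC scaffold; 17 kPa, the mean
#'   nuclear-envelope elasticity, for want of direct measurements.
#' @param cross_section_nm2 effective cross-sectional area of a scaffold
#'   rod element (nm^2).
#' @param k_bend_scaffold scaffold bending constant (kT); 100 kT, the
#'   smallest value that keeps the subunits assembled during transport.
#' @return a list of material parameters.
#' @export
scaffold_material <- function(E_young_kPa = 17, cross_section_nm2 = 100,
                              k_bend_scaffold = 100) {
  if (E_young_kPa <= 0 || cross_section_nm2 <= 0 || k_bend_scaffold <= 0) {
    abort("material parameters must be positive", class = "npcbd_domain_error")
  }
  list(E_young_kPa = E_young_kPa, cross_section_nm2 = cross_section_nm2,
       k_bend_scaffold = k_bend_scaffold)
}

# Hourglass wall half-width at axial position y (quadratic profile).
wall_radius <- function(y, config) {
  mid <- -config$channel_length / 2
  half <- config$channel_length / 2
  t <- (y - mid) / half
  config$channel_min_diameter / 2 +
    (config$channel_entrance_diameter - config$channel_min_diameter) / 2 * t^2
}

# interpolate n_seg+1 points from a to b (2-column), inclusive
.rod_points <- function(a, b, n_seg) {
  t <- seq(0, 1, length.out = n_seg + 1)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
}

.angle_at <- function(p_i, p_j, p_k) {
  a <- p_i - p_j
  b <- p_k - p_j
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ct)))
}

#' Build the elastic two-spoke NPC scaffold
#'
#' Discretizes cytoplasmic filaments, the hourglass channel walls and the
#' nuclear basket rods into bead-spring rods, ties the channel walls to the
#' rigid nuclear envelope with pom springs, and closes the basket with a
#' distal-ring bond. All bonds are built at rest length and all bending
#' angles at their as-built equilibrium, so the assembled structure is
#' stress-free.
#'
#' @param config a [geometry_config()].
#' @param material a [scaffold_material()].
#' @param viscosity_cP,temperature_K conditions used to assign per-bead drag
#'   and diffusion coefficients (Stokes spheres).
#' @return an `npc_structure` with tibbles `beads`, `bonds`, `angles`, plus
#'   empty chain tables ready for [graft_fg_chains()].
#' @export
build_scaffold <- function(config = geometry_config(),
                           material = scaffold_material(),
                           viscosity_cP = 5, temperature_K = 310) {
  stopifnot(inherits(config, "geometry_config"))
  sp <- config$scaffold_bead_spacing
  L_ch <- config$channel_length
  r_entr <- config$channel_entrance_diameter / 2
  r_distal <- config$distal_ring_diameter / 2
  y_exit <- -L_ch - config$basket_length

  beads <- list(); bonds <- list(); angles <- list()
  nid <- 0L
  add_beads <- function(xy, group, region, spoke) {
    ids <- nid + seq_len(nrow(xy))
    nid <<- nid + nrow(xy)
    beads[[length(beads) + 1L]] <<- tibble(
      id = as.integer(ids), x = xy[, 1], y = xy[, 2],
      group = group, region = region, spoke = spoke)
    as.integer(ids)
  }
  kb <- material$k_bend_scaffold
  k_of <- function(r0) spring_constant_from_modulus(
    material$E_young_kPa, material$cross_section_nm2, r0, temperature_K)
  add_rod_bonds <- function(ids, pts) {
    for (b in seq_len(length(ids) - 1)) {
      r0 <- sqrt(sum((pts[b + 1, ] - pts[b, ])^2))
      bonds[[length(bonds) + 1L]] <<- tibble(
        i = ids[b], j = ids[b + 1], k_s = k_of(r0), r0 = r0, kind = "scaffold")
    }
  }
  add_rod_angles <- function(ids, pts) {
    if (length(ids) < 3) return(invisible())
    for (a in seq_len(length(ids) - 2)) {
      t0 <- .angle_at(pts[a, ], pts[a + 1, ], pts[a + 2, ])
      angles[[length(angles) + 1L]] <<- tibble(
        i = ids[a], j = ids[a + 1], k = ids[a + 2], k_theta = kb, theta0 = t0)
    }
  }

  distal_ids <- integer(0)
  for (s in c(1, -1)) {
    # hourglass channel wall
    n_wall <- ceiling(L_ch / sp)
    yw <- seq(0, -L_ch, length.out = n_wall + 1)
    wall_pts <- cbind(s * wall_radius(yw, config), yw)
    wall_ids <- add_beads(wall_pts, "scaffold", "channel", s)
    add_rod_bonds(wall_ids, wall_pts)
    add_rod_angles(wall_ids, wall_pts)

    # pom anchors: one per wall bead, fixed to the envelope
    anch_pts <- cbind(wall_pts[, 1] + s * config$pom_spring_length, yw)
    anch_ids <- add_beads(anch_pts, "pom_anchor", "envelope", s)
    for (b in seq_along(wall_ids)) {
      bonds[[length(bonds) + 1L]] <- tibble(
        i = wall_ids[b], j = anch_ids[b],
        k_s = k_of(config$pom_spring_length),
        r0 = config$pom_spring_length, kind = "pom")
    }

    # cytoplasmic filament rising from the wall top
    n_fil <- ceiling(config$filament_length / sp)
    fil_pts_all <- .rod_points(wall_pts[1, ],
                               c(s * r_entr, config$filament_length), n_fil)
    fil_ids_new <- add_beads(fil_pts_all[-1, , drop = FALSE],
                             "scaffold", "filament", s)
    fil_ids <- c(wall_ids[1], fil_ids_new)
    add_rod_bonds(fil_ids, fil_pts_all)
    add_rod_angles(fil_ids, fil_pts_all)

    # nuclear basket rod slanting from the wall bottom to the distal ring
    bot <- wall_pts[nrow(wall_pts), ]
    distal <- c(s * r_distal, y_exit)
    n_bask <- ceiling(sqrt(sum((distal - bot)^2)) / sp)
    bask_pts_all <- .rod_points(bot, distal, n_bask)
    bask_ids_new <- add_beads(bask_pts_all[-1, , drop = FALSE],
                              "scaffold", "basket", s)
    bask_ids <- c(wall_ids[length(wall_ids)], bask_ids_new)
    add_rod_bonds(bask_ids, bask_pts_all)
    add_rod_angles(bask_ids, bask_pts_all)
    distal_ids <- c(distal_ids, bask_ids[length(bask_ids)])
  }

  beads <- bind_rows(beads)
  # distal ring: tie the two rod ends across the axis
  d0 <- abs(diff(beads$x[match(distal_ids, beads$id)]))
  bonds[[length(bonds) + 1L]] <- tibble(
    i = distal_ids[1], j = distal_ids[2], k_s = k_of(d0), r0 = d0,
    kind = "ring")
  bonds <- bind_rows(bonds)
  angles <- bind_rows(angles)

  beads$radius <- ifelse(beads$group == "pom_anchor", 0,
                         config$scaffold_bead_radius)
  beads$mobile <- beads$group != "pom_anchor"
  beads$chain_id <- NA_integer_
  beads <- .bead_hydrodynamics(beads, viscosity_cP, temperature_K)

  structure(list(
    beads = beads, bonds = bonds, angles = angles,
    chains = tibble(chain_id = integer(), region = character(),
                    cohesive = logical(), graft_bead = integer(),
                    bead_ids = list(), segment_contour = double(),
                    persistence = double()),
    wlc = tibble(i = integer(), j = integer(), L_s = double(),
                 l_p = double(), chain_id = integer()),
    config = config, material = material,
    conditions = list(viscosity_cP = viscosity_cP,
                      temperature_K = temperature_K),
    planes = list(entry = config$filament_length, channel_top = 0,
                  mid_channel = -L_ch / 2, channel_bottom = -L_ch,
                  basket_top = -L_ch, exit = y_exit),
    wall = list(y_lo = -L_ch, y_hi = 0,
                r_waist = config$channel_min_diameter / 2,
                r_entr = r_entr, margin = config$wall_margin)
  ), class = "npc_structure")
}

.bead_hydrodynamics <- function(beads, viscosity_cP, temperature_K) {
  mobile_r <- ifelse(beads$radius > 0, beads$radius, 1)
  drag <- stokes_drag(mobile_r, viscosity_cP)
  beads$mass_kg <- ifelse(beads$radius > 0,
                          bead_mass_from_radius(mobile_r), 0)
  beads$drag <- ifelse(beads$radius > 0, drag, Inf)
  beads$diffusion <- ifelse(beads$radius > 0,
                            diffusion_from_drag(drag, temperature_K), 0)
  beads
}

# forbidden-region test mirroring the engine's rigid envelope
.in_envelope <- function(x, y, structure) {
  w <- structure$wall
  y >= w$y_lo & y <= w$y_hi &
    abs(x) >= wall_radius(y, structure$config) + w$margin
}

#' Graft FG-repeat chains onto the scaffold
#'
#' Attaches discrete-WLC FG-repeat domains at graft sites on the cytoplasmic
#' filaments, the channel wall and the basket rods. Short chains
#' (`fg_central_contour`, cohesive) line the central channel; long chains
#' (`fg_peripheral_contour`, noncohesive) occupy both peripheries. Each
#' chain is cut into `contour / segment_length` WLC segments with one
#' FG-motif bead per segment endpoint, and the motif budget is split evenly
#' between the three regions. Initial conformations are self-avoiding random
#' walks with step 0.8 L_s, kept out of the rigid envelope (seeded, so the
#' build is reproducible).
#'
#' @param structure an `npc_structure` from [build_scaffold()].
#' @param config the [geometry_config()] (defaults to the one stored in
#'   `structure`).
#' @param l_p persistence length (nm).
#' @param seed integer seed for the initial conformations.
#' @return the structure with FG beads, WLC segments, chain bending angles
#'   and the chain table filled in.
#' @export
graft_fg_chains <- function(structure, config = structure$config,
                            l_p = config$persistence_length, seed = 1) {
  stopifnot(inherits(structure, "npc_structure"))
  if (nrow(structure$chains) > 0) {
    abort("structure already has FG chains", class = "npcbd_config_error")
  }
  Ls <- config$fg_segment_length
  m_central <- as.integer(ceiling(config$fg_central_contour / Ls))
  m_periph <- as.integer(ceiling(config$fg_peripheral_contour / Ls))
  total <- config$fg_total_motifs
  w <- config$fg_region_weights / sum(config$fg_region_weights)
  targets <- total * w # filament, channel, basket
  m_of <- c(m_periph, m_central, m_periph)
  n_chains <- targets / m_of
  ok <- function(v) all(abs(v - round(v)) < 1e-9 & round(v) >=
                          config$n_spokes &
                          round(v) %% config$n_spokes == 0)
  if (!ok(n_chains)) {
    ach <- pmax(config$n_spokes,
                floor(n_chains / config$n_spokes) * config$n_spokes)
    achievable <- sum(ach * m_of)
    abort(sprintf(paste0(
      "cannot place %d FG motifs exactly with these chain lengths and ",
      "region weights; nearest achievable count is %d"), total, achievable),
      class = "npcbd_config_error")
  }
  n_chains <- as.integer(round(n_chains))
  n_ch_fil <- n_chains[1]
  n_ch_central <- n_chains[2]
  n_ch_bask <- n_chains[3]

  beads <- structure$beads
  graft_sites <- function(region, n_chains_per_spoke) {
    out <- integer(0)
    for (s in c(1, -1)) {
      ids <- beads$id[beads$region == region & beads$spoke == s &
                        beads$group == "scaffold"]
      out <- c(out, rep(ids, length.out = n_chains_per_spoke))
    }
    out
  }
  plan <- bind_rows(
    tibble(region = "filament", graft = graft_sites("filament", n_ch_fil / 2),
           m = m_periph, contour = config$fg_peripheral_contour,
           cohesive = FALSE, group = "fg_peripheral"),
    tibble(region = "channel", graft = graft_sites("channel", n_ch_central / 2),
           m = m_central, contour = config$fg_central_contour,
           cohesive = TRUE, group = "fg_central"),
    tibble(region = "basket", graft = graft_sites("basket", n_ch_bask / 2),
           m = m_periph, contour = config$fg_peripheral_contour,
           cohesive = FALSE, group = "fg_peripheral"))

  step_len <- 0.8 * Ls
  placed <- matrix(numeric(0), ncol = 2)
  new_beads <- list(); new_wlc <- list(); new_angles <- list()
  chains <- list()
  nid <- max(beads$id)
  kth <- wlc_bending_constant(l_p, Ls)

  withr::with_seed(seed, {
    for (ci in seq_len(nrow(plan))) {
      graft_id <- plan$graft[ci]
      g <- c(beads$x[beads$id == graft_id], beads$y[beads$id == graft_id])
      # initial direction: into the open compartment
      dir0 <- switch(plan$region[ci],
                     channel = c(-sign(g[1]), 0),
                     filament = c(sign(g[1]) * 0.3, 1),
                     basket = c(-sign(g[1]) * 0.3, -0.5))
      dir0 <- dir0 / sqrt(sum(dir0^2))
      pts <- matrix(0, plan$m[ci], 2)
      cur <- g; dir <- dir0
      for (b in seq_len(plan$m[ci])) {
        best <- NULL
        for (try in seq_len(40)) {
          ang <- atan2(dir[2], dir[1]) +
            stats::runif(1, -pi / 3, pi / 3) * (if (b == 1) 0.5 else 1)
          cand <- cur + step_len * c(cos(ang), sin(ang))
          if (.in_envelope(cand[1], cand[2], structure)) next
          if (is.null(best)) best <- cand
          if (nrow(placed) == 0 ||
              min((placed[, 1] - cand[1])^2 +
                    (placed[, 2] - cand[2])^2) > 1.0) {
            best <- cand
            break
          }
        }
        if (is.null(best)) { # squeeze toward the pore axis
          best <- cur + step_len * c(-sign(cur[1]), 0)
        }
        pts[b, ] <- best
        placed <- rbind(placed, best)
        dir <- (best - cur) / step_len
        cur <- best
      }
      ids <- nid + seq_len(plan$m[ci])
      nid <- nid + plan$m[ci]
      new_beads[[ci]] <- tibble(
        id = as.integer(ids), x = pts[, 1], y = pts[, 2],
        group = plan$group[ci], region = plan$region[ci],
        spoke = sign(g[1]), radius = config$fg_bead_radius, mobile = TRUE,
        chain_id = ci)
      chain_path <- c(graft_id, ids)
      new_wlc[[ci]] <- tibble(
        i = as.integer(chain_path[-length(chain_path)]),
        j = as.integer(chain_path[-1]), L_s = Ls, l_p = l_p, chain_id = ci)
      if (length(chain_path) >= 3) {
        n3 <- length(chain_path) - 2
        new_angles[[ci]] <- tibble(
          i = as.integer(chain_path[seq_len(n3)]),
          j = as.integer(chain_path[seq_len(n3) + 1]),
          k = as.integer(chain_path[seq_len(n3) + 2]),
          k_theta = kth, theta0 = pi)
      }
      chains[[ci]] <- tibble(
        chain_id = ci, region = plan$region[ci], cohesive = plan$cohesive[ci],
        graft_bead = as.integer(graft_id), bead_ids = list(as.integer(ids)),
        segment_contour = Ls, persistence = l_p)
    }
  })

  nb <- bind_rows(new_beads)
  nb <- .bead_hydrodynamics(nb, structure$conditions$viscosity_cP,
                            structure$conditions$temperature_K)
  structure$beads <- bind_rows(beads, nb)
  structure$wlc <- bind_rows(structure$wlc, bind_rows(new_wlc))
  structure$angles <- bind_rows(structure$angles, bind_rows(new_angles))
  structure$chains <- bind_rows(chains)
  stopifnot(count_fg_motifs(structure) == total)
  structure
}

#' Build the default NPC (scaffold + FG chains)
#'
#' @inheritParams build_scaffold
#' @inheritParams graft_fg_chains
#' @return a complete `npc_structure`.
#' @export
build_npc <- function(config = geometry_config(),
                      material = scaffold_material(), seed = 1,
                      viscosity_cP = 5, temperature_K = 310) {
  build_scaffold(config, material, viscosity_cP, temperature_K) |>
    graft_fg_chains(config, seed = seed)
}

#' Count FG-motif beads in a structure
#' @param structure an `npc_structure`.
#' @return integer motif count.
#' @export
count_fg_motifs <- function(structure) {
  sum(structure$beads$group %in% c("fg_central", "fg_peripheral"))
}

#' Per-NPC FG-motif density implied by the cross-sectional model
#'
#' Scales the two-spoke motif count up to the eight-spoke pore; the
#' wild-type NPC carries ~2700-3000 motifs.
#'
#' @param structure an `npc_structure`.
#' @return scaled motif count.
#' @export
fg_density_scaled <- function(structure) {
  count_fg_motifs(structure) * 8 / structure$config$n_spokes
}

#' Remove the cytoplasmic filaments and their FG chains
#'
#' The filament-deficient pore used in the inert-cargo selectivity
#' experiment: filament scaffold beads, their bonds and bending angles, and
#' every FG chain grafted on a filament are removed; channel and basket are
#' untouched.
#'
#' @param structure an `npc_structure`.
#' @return the ablated structure (bead ids are renumbered contiguously).
#' @export
delete_cytoplasmic_filaments <- function(structure) {
  stopifnot(inherits(structure, "npc_structure"))
  fil_scaffold <- structure$beads$id[structure$beads$region == "filament" &
                                       structure$beads$group == "scaffold"]
  fil_chains <- structure$chains$chain_id[structure$chains$region == "filament"]
  if (length(fil_scaffold) == 0 && length(fil_chains) == 0) {
    warn("structure has no cytoplasmic filaments; returning it unchanged")
    return(structure)
  }
  drop_beads <- c(fil_scaffold,
                  unlist(structure$chains$bead_ids[
                    structure$chains$chain_id %in% fil_chains]))
  keep <- setdiff(structure$beads$id, drop_beads)
  remap <- stats::setNames(seq_along(keep), keep)
  rid <- function(v) as.integer(remap[as.character(v)])
  touches <- function(...) {
    cols <- list(...)
    Reduce(`|`, lapply(cols, function(v) v %in% drop_beads))
  }
  structure$beads <- structure$beads |>
    filter(!.data$id %in% drop_beads) |>
    mutate(id = rid(.data$id))
  structure$bonds <- structure$bonds |>
    filter(!touches(.data$i, .data$j)) |>
    mutate(i = rid(.data$i), j = rid(.data$j))
  structure$angles <- structure$angles |>
    filter(!touches(.data$i, .data$j, .data$k)) |>
    mutate(i = rid(.data$i), j = rid(.data$j), k = rid(.data$k))
  structure$wlc <- structure$wlc |>
    filter(!touches(.data$i, .data$j)) |>
    mutate(i = rid(.data$i), j = rid(.data$j))
  structure$chains <- structure$chains |>
    filter(!.data$chain_id %in% fil_chains) |>
    mutate(graft_bead = rid(.data$graft_bead),
           bead_ids = map(.data$bead_ids, rid))
  structure
}

#' @export
print.npc_structure <- function(x, ...) {
  cat("<npc_structure>\n")
  cat(sprintf("  beads: %d (%d scaffold, %d FG, %d anchors)\n",
              nrow(x$beads), sum(x$beads$group == "scaffold"),
              count_fg_motifs(x), sum(x$beads$group == "pom_anchor")))
  cat(sprintf("  bonds: %d, angles: %d, WLC segments: %d, chains: %d\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$wlc), nrow(x$chains)))
  cat(sprintf("  transport span: %g nm (entry y=%g to exit y=%g)\n",
              x$config$transport_span, x$planes$entry, x$planes$exit))
  invisible(x)
}

#' Structural invariants check
#'
#' Verifies that every mobile bead takes part in at least one bond or WLC
#' segment, that the motif count matches the configuration, and that
#' diffusion and drag satisfy the fluctuation-dissipation relation.
#'
#' @param structure an `npc_structure`.
#' @return invisibly `TRUE`; aborts on violation.
#' @export
validate_structure <- function(structure) {
  connected <- unique(c(structure$bonds$i, structure$bonds$j,
                        structure$wlc$i, structure$wlc$j))
  lonely <- setdiff(structure$beads$id[structure$beads$mobile], connected)
  if (length(lonely) > 0) {
    abort(sprintf("mobile beads not in any bond or chain: %s",
                  paste(utils::head(lonely), collapse = ", ")))
  }
  if (nrow(structure$chains) > 0 &&
      count_fg_motifs(structure) !=
      sum(lengths(structure$chains$bead_ids))) {
    abort("FG bead count does not match the chain table")
  }
  kT <- kT_joules(structure$conditions$temperature_K)
  mob <- structure$beads[structure$beads$mobile, ]
  dd <- mob$diffusion * 1e-12 * mob$drag # um^2/s -> m^2/s times kg/s
  if (any(abs(dd - kT) / kT > 1e-9)) {
    abort("diffusion * drag != kT for some bead")
  }
  invisible(TRUE)
}
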