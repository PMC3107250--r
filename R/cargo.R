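# The cargo-complex: a rigid sphere (NLS-cargo + kap-beta) carrying a
# body-fixed 'hydrophobic arc with limited capacity' - eight binding spots
# equally spaced over a semicircle on its surface. A cargo with no spots is
# inert: it keeps its excluded volume but has no hydrophobic affinity.

#' Create a cargo-complex
#'
#' @param diameter cargo diameter in nm (the transport experiments use 3,
#'   9, 15 and 20).
#' @param n_spots number of hydrophobic binding spots on the kap surface
#'   (8 for an active cargo-complex; 0 gives an inert cargo).
#' @param kap_fg the kap-FG [hydrophobic_rule()] shared by all spots
#'   (every spot has the same affinity).
#' @param arc_deg angular span of the binding arc (180: a semicircular
#'   stripe).
#' @param orientation_deg direction of the arc bisector, measured from the
#'   +x axis; the arc is body-fixed and the sphere does not rotate.
#' @param viscosity_cP,temperature_K conditions for the Stokes drag of the
#'   sphere.
#' @return a `cargo` object with spot offsets (nm, body frame), drag (kg/s)
#'   and diffusion coefficient (um^2/s).
#' @examples
#' make_cargo(15, 8)$diffusion # ~6.1 um^2/s
#' @export
make_cargo <- function(diameter = 15, n_spots = 8,
                       kap_fg = hydrophobic_rule(2, 1.5),
                       arc_deg = 180, orientation_deg = 0,
                       viscosity_cP = 5, temperature_K = 310) {
  if (diameter <= 0 || n_spots < 0) {
    abort("diameter must be positive and n_spots non-negative",
          class = "npcbd_domain_error")
  }
  R <- diameter / 2
  if (n_spots == 0) {
    offs <- matrix(numeric(0), ncol = 2)
  } else if (n_spots == 1) {
    offs <- matrix(c(R, 0), ncol = 2)
  } else {
    half <- arc_deg / 2 * pi / 180
    ang <- orientation_deg * pi / 180 + seq(-half, half, length.out = n_spots)
    offs <- cbind(R * cos(ang), R * sin(ang))
  }
  drag <- stokes_drag(R, viscosity_cP)
  structure(list(
    diameter = diameter, radius = R, n_binding_spots = as.integer(n_spots),
    spot_offsets = offs, kap_fg = kap_fg, active = n_spots > 0,
    drag = drag, diffusion = diffusion_from_drag(drag, temperature_K)
  ), class = "cargo")
}

#' @export
print.cargo <- function(x, ...) {
  cat(sprintf("<cargo> %g nm %s, %d binding spots, D = %.2f um^2/s\n",
              x$diameter, if (x$active) "active" else "inert",
              x$n_binding_spots, x$diffusion))
  invisible(x)
}

#' Place a cargo at the cytoplasmic entry
#'
#' Centers the cargo on the pore axis above the filament tips, at a standoff
#' of one cargo diameter by default, then raises it (deterministically) until
#' every binding spot and the cargo surface are outside the kap-FG cutoff of
#' all FG beads, so that the start-of-transport event is detected
#' dynamically rather than at t = 0.
#'
#' @param structure an `npc_structure`.
#' @param cargo a [make_cargo()] object.
#' @param standoff initial axial clearance above the filament tips (nm).
#' @param positions optional N x 2 matrix of current bead positions (e.g.
#'   after equilibration); defaults to the as-built coordinates.
#' @return length-2 numeric position (x, y) for the cargo center.
#' @export
place_cargo_at_entry <- function(structure, cargo,
                                 standoff = cargo$diameter,
                                 positions = NULL) {
  stopifnot(inherits(structure, "npc_structure"), inherits(cargo, "cargo"))
  if (standoff < 0) {
    abort("standoff would place the cargo inside the structure",
          class = "npcbd_placement_error")
  }
  if (is.null(positions)) {
    positions <- cbind(structure$beads$x, structure$beads$y)
  }
  fg <- structure$beads$group %in% c("fg_central", "fg_peripheral")
  y <- structure$planes$entry + standoff + cargo$radius
  cutoff <- cargo$kap_fg$cutoff
  for (attempt in seq_len(200)) {
    pos <- c(0, y)
    if (!any(fg)) break
    pts <- rbind(pos, sweep(cargo$spot_offsets, 2, pos, `+`))
    dmin <- min(sqrt(outer(pts[, 1], positions[fg, 1], `-`)^2 +
                       outer(pts[, 2], positions[fg, 2], `-`)^2))
    dsurf <- min(sqrt((positions[fg, 1] - pos[1])^2 +
                        (positions[fg, 2] - pos[2])^2)) - cargo$radius
    if (dmin > cutoff && dsurf > cutoff) break
    y <- y + 2
  }
  c(0, y)
}
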