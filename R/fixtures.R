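# Miniature, fast-building systems used throughout the test suite and for
# demonstrations. Every fixture is deterministic and runs in seconds.

.bare_structure <- function(beads, bonds = NULL, wlc = NULL, angles = NULL,
                            viscosity_cP = 5, temperature_K = 310) {
  empty_bonds <- tibble(i = integer(), j = integer(), k_s = double(),
                        r0 = double(), kind = character())
  empty_angles <- tibble(i = integer(), j = integer(), k = integer(),
                         k_theta = double(), theta0 = double())
  empty_wlc <- tibble(i = integer(), j = integer(), L_s = double(),
                      l_p = double(), chain_id = integer())
  beads <- .bead_hydrodynamics(beads, viscosity_cP, temperature_K)
  structure(list(
    beads = beads, bonds = bonds %||% empty_bonds,
    angles = angles %||% empty_angles,
    chains = tibble(chain_id = integer(), region = character(),
                    cohesive = logical(), graft_bead = integer(),
                    bead_ids = list(), segment_contour = double(),
                    persistence = double()),
    wlc = wlc %||% empty_wlc,
    config = NULL, material = NULL,
    conditions = list(viscosity_cP = viscosity_cP,
                      temperature_K = temperature_K),
    planes = list(entry = 0, channel_top = 0, mid_channel = 0,
                  channel_bottom = 0, basket_top = 0, exit = 0),
    wall = list(y_lo = 0, y_hi = 0, r_waist = 1, r_entr = 1, margin = 0)
  ), class = "npc_structure")
}

#' Miniature test systems
#'
#' Named fixtures:
#' \describe{
#'   \item{free_bead}{one untethered bead (default radius 0.9 nm, so
#'     D ~ 50 um^2/s): free-diffusion/MSD checks.}
#'   \item{harmonic_well}{one bead bound to a fixed anchor by a harmonic
#'     spring with `r0 = 0` (default k = 1 kT/nm^2): Boltzmann-statistics
#'     check of the integrator noise scaling.}
#'   \item{single_wlc_chain}{a 5-segment discrete WLC (L_s = 10 nm,
#'     l_p = 0.43 nm) tethered to a fixed graft point: extensibility and
#'     rejection checks.}
#'   \item{mini_npc}{a complete scaled-down pore (90 nm span, 40 nm
#'     waist, 288 FG motifs). Filament and channel brushes keep the full
#'     model's local FG density and the peripheral chain contour (90 nm)
#'     is chosen so the chains' random-walk extent covers the entrance
#'     radius, as the 200 nm chains do in the full geometry; the basket
#'     brush is thinner so the completion region stays accessible at the
#'     reduced basket size. Comes with a 15 nm 8-spot cargo. Used for
#'     end-to-end smoke and surrogate transport tests.}
#' }
#'
#' @param name fixture name.
#' @param overrides named list of parameter overrides (fixture-specific:
#'   `radius`, `k_s`, `n_segments`, or any [geometry_config()] argument and
#'   `cargo_diameter`/`cargo_spots` for `mini_npc`; `seed` everywhere).
#' @return a list with `structure`, `cargo` (mini_npc only, else `NULL`)
#'   and `wall_on`.
#' @export
make_fixture <- function(name, overrides = list()) {
  ov <- function(key, default) overrides[[key]] %||% default
  seed <- ov("seed", 1)
  switch(
    name,
    free_bead = {
      beads <- tibble(id = 1L, x = 0, y = 0, group = "scaffold",
                      region = "free", spoke = 1, radius = ov("radius", 0.9),
                      mobile = TRUE, chain_id = NA_integer_)
      list(structure = .bare_structure(beads), cargo = NULL, wall_on = FALSE)
    },
    harmonic_well = {
      beads <- tibble(id = 1:2, x = c(0, 1), y = c(0, 0),
                      group = c("pom_anchor", "scaffold"),
                      region = "well", spoke = 1,
                      radius = c(0, ov("radius", 0.9)),
                      mobile = c(FALSE, TRUE), chain_id = NA_integer_)
      bonds <- tibble(i = 1L, j = 2L, k_s = ov("k_s", 1), r0 = 0,
                      kind = "well")
      list(structure = .bare_structure(beads, bonds), cargo = NULL,
           wall_on = FALSE)
    },
    single_wlc_chain = {
      n <- ov("n_segments", 5)
      Ls <- ov("segment_length", 10)
      lp <- ov("persistence", 0.43)
      x <- c(0, cumsum(rep(0.8 * Ls, n)))
      beads <- tibble(id = seq_len(n + 1), x = x, y = 0,
                      group = c("pom_anchor", rep("fg_central", n)),
                      region = "chain", spoke = 1,
                      radius = c(0, rep(0.9, n)),
                      mobile = c(FALSE, rep(TRUE, n)),
                      chain_id = c(NA_integer_, rep(1L, n)))
      wlc <- tibble(i = seq_len(n), j = seq_len(n) + 1L, L_s = Ls,
                    l_p = lp, chain_id = 1L)
      kth <- wlc_bending_constant(lp, Ls)
      angles <- if (n >= 2) {
        tibble(i = seq_len(n - 1), j = seq_len(n - 1) + 1L,
               k = seq_len(n - 1) + 2L, k_theta = kth, theta0 = pi)
      } else NULL
      st <- .bare_structure(beads, wlc = wlc, angles = angles)
      st$chains <- tibble(chain_id = 1L, region = "chain", cohesive = TRUE,
                          graft_bead = 1L,
                          bead_ids = list(2:(n + 1L)),
                          segment_contour = Ls, persistence = lp)
      list(structure = st, cargo = NULL, wall_on = FALSE)
    },
    mini_npc = {
      geo_keys <- names(formals(geometry_config))
      geo_over <- overrides[intersect(names(overrides), geo_keys)]
      geo_args <- utils::modifyList(list(
        channel_min_diameter = 40, channel_entrance_diameter = 48,
        channel_length = 30, filament_length = 20, basket_length = 40,
        distal_ring_diameter = 28, fg_total_motifs = 288,
        fg_central_contour = 30, fg_peripheral_contour = 90,
        fg_region_weights = c(filament = 7, channel = 6, basket = 3),
        fg_segment_length = 10), geo_over)
      cfg <- do.call(geometry_config, geo_args)
      st <- build_npc(cfg, seed = seed)
      cargo <- make_cargo(ov("cargo_diameter", 15), ov("cargo_spots", 8))
      list(structure = st, cargo = cargo, wall_on = TRUE)
    },
    abort(sprintf(
      "unknown fixture '%s'; available: free_bead, harmonic_well, %s",
      name, "single_wlc_chain, mini_npc"), class = "npcbd_config_error")
  )
}
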