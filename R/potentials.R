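# The five pair/bonded potentials of the model, as vectorized reference
# implementations. The simulation engine re-implements the same algebra in
# C++; the R versions are the user-facing/documented forms and the oracle
# used by the gradient and neighbor-list tests.
#
# Sign convention for radial terms: `force` is the component of the force on
# the outer bead along the separation unit vector, i.e. force = -dE/dr.
# Negative values pull the pair together (attraction).

#' Harmonic spring energy and force
#'
#' E = 1/2 k_s (r - r0)^2 between consecutive scaffold beads and in pom
#' springs.
#'
#' @param r separation in nm (>= 0).
#' @param k_s spring constant in kT/nm^2.
#' @param r0 equilibrium bond length in nm.
#' @return a tibble with columns `energy` (kT) and `force` (kT/nm,
#'   -dE/dr; negative = attractive).
#' @export
harmonic <- function(r, k_s, r0) {
  stopifnot(all(r >= 0), all(k_s > 0), all(r0 > 0))
  tibble(energy = 0.5 * k_s * (r - r0)^2,
         force  = -k_s * (r - r0))
}

#' Cosine bending energy and torque
#'
#' E = k_theta (1 - cos(theta - theta0)) between two consecutive segments,
#' applied to the main scaffold (k_theta = 100 kT) and, with the much
#' smaller constant from [wlc_bending_constant()], to FG chains. For small
#' deflections it reduces to the harmonic form k_theta/2 (theta - theta0)^2.
#'
#' @param theta bond angle in radians, in `[0, pi]`.
#' @param k_theta bending force constant in kT.
#' @param theta0 equilibrium angle in radians.
#' @return a tibble with columns `energy` (kT) and `torque`
#'   (kT/rad, -dE/dtheta).
#' @export
cosine_bending <- function(theta, k_theta, theta0) {
  stopifnot(all(theta >= 0), all(theta <= pi + 1e-12), all(k_theta > 0))
  tibble(energy = k_theta * (1 - cos(theta - theta0)),
         torque = -k_theta * sin(theta - theta0))
}

#' Marko-Siggia wormlike-chain restoring force
#'
#' F = (kT/l_p) (1/(4 (1 - x/L_s)^2) - 1/4 + x/L_s), the interpolation
#' force-law of a WLC segment. The force is restoring (pulls the bead pair
#' together) and diverges as the extension approaches the contour length;
#' the integrator's rejection scheme keeps extensions strictly below L_s.
#'
#' @param extension segment extension x in nm, `0 <= x < L_s`.
#' @param L_s segment contour length in nm.
#' @param l_p persistence length in nm (0.43 for FG domains).
#' @return restoring force magnitude in kT/nm.
#' @export
wlc_force <- function(extension, L_s, l_p) {
  stopifnot(all(L_s > 0), all(l_p > 0), all(extension >= 0))
  if (any(extension >= L_s)) {
    abort("WLC extension at or beyond the contour length",
          class = "npcbd_extensibility_error")
  }
  x <- extension / L_s
  (1 / l_p) * (1 / (4 * (1 - x)^2) - 0.25 + x)
}

#' Hydrophobic pair rule
#'
#' Parameters of the long-range hydrophobic attraction: affinity strength
#' epsilon (1.5-10 kT admissible), characteristic decay length xi (1-2 nm),
#' and the 10 nm cutoff. Model defaults: kap-FG epsilon = 2 kT, xi = 1.5 nm;
#' FG-FG epsilon = 1.5 kT, xi = 1 nm (central FG beads only - peripheral FG
#' beads have no mutual affinity).
#'
#' @param epsilon affinity strength in kT.
#' @param xi characteristic length in nm.
#' @param cutoff cutoff radius in nm.
#' @return an object of class `hydrophobic_rule`.
#' @export
hydrophobic_rule <- function(epsilon, xi, cutoff = 10) {
  stopifnot(epsilon > 0, xi > 0, cutoff > 0)
  structure(list(epsilon = epsilon, xi = xi, cutoff = cutoff),
            class = "hydrophobic_rule")
}

#' Soft repulsive pair rule
#'
#' Parameters of the short-range excluded-volume repulsion: well depth 100
#' kT, characteristic length sigma = 1 nm, cutoff 1.35 nm. The potential is
#' finite at contact, which permits the large diffusive time step.
#'
#' @param epsilon_rep well depth in kT.
#' @param sigma characteristic length in nm.
#' @param cutoff cutoff radius in nm.
#' @return an object of class `repulsive_rule`.
#' @export
repulsive_rule <- function(epsilon_rep = 100, sigma = 1, cutoff = 1.35) {
  stopifnot(epsilon_rep > 0, sigma > 0, cutoff > 0)
  structure(list(epsilon_rep = epsilon_rep, sigma = sigma, cutoff = cutoff),
            class = "repulsive_rule")
}

#' Hydrophobic attraction energy and force
#'
#' E(r) = -epsilon (exp(-r/xi) - exp(-cutoff/xi)) for r < cutoff, 0 beyond:
#' a single-exponential decay, shifted so the energy is continuous at the
#' cutoff. Attractive at all r inside the cutoff.
#'
#' @param r pair separation in nm (>= 0).
#' @param rule a [hydrophobic_rule()].
#' @return a tibble with columns `energy` (kT) and `force` (kT/nm, -dE/dr).
#' @export
hydrophobic <- function(r, rule) {
  stopifnot(inherits(rule, "hydrophobic_rule"), all(r >= 0))
  inside <- r < rule$cutoff
  shift <- exp(-rule$cutoff / rule$xi)
  tibble(
    energy = ifelse(inside, -rule$epsilon * (exp(-r / rule$xi) - shift), 0),
    force  = ifelse(inside, -(rule$epsilon / rule$xi) * exp(-r / rule$xi), 0)
  )
}

#' Soft repulsive energy and force
#'
#' E(r) = epsilon_rep (exp(-r/sigma) - exp(-cutoff/sigma)) for r < cutoff,
#' 0 beyond. Finite at r = 0 and monotone non-increasing.
#'
#' @param r pair separation in nm (>= 0). For bead-cargo pairs r is the
#'   bead-center to cargo-surface distance, so it may be supplied negative
#'   when a bead penetrates the cargo surface; the energy stays finite.
#' @param rule a [repulsive_rule()].
#' @return a tibble with columns `energy` (kT) and `force` (kT/nm, -dE/dr;
#'   positive = repulsive).
#' @export
soft_repulsive <- function(r, rule = repulsive_rule()) {
  stopifnot(inherits(rule, "repulsive_rule"))
  inside <- r < rule$cutoff
  shift <- exp(-rule$cutoff / rule$sigma)
  tibble(
    energy = ifelse(inside,
                    rule$epsilon_rep * (exp(-r / rule$sigma) - shift), 0),
    force  = ifelse(inside,
                    (rule$epsilon_rep / rule$sigma) * exp(-r / rule$sigma), 0)
  )
}

#' Default interaction rule set
#'
#' The nonbonded interaction matrix of the model: FG-FG hydrophobic
#' attraction among central-channel FG beads only, kap-FG attraction between
#' cargo binding spots and every FG bead, and soft repulsion between all
#' nonbonded pairs (including the cargo body, measured center-to-surface).
#'
#' @param fg_fg [hydrophobic_rule()] for central FG-FG pairs.
#' @param kap_fg [hydrophobic_rule()] for binding-spot/FG pairs.
#' @param repulsion [repulsive_rule()] for all nonbonded pairs.
#' @return an object of class `interaction_rules`.
#' @export
interaction_rules <- function(fg_fg = hydrophobic_rule(1.5, 1.0),
                              kap_fg = hydrophobic_rule(2.0, 1.5),
                              repulsion = repulsive_rule()) {
  stopifnot(inherits(fg_fg, "hydrophobic_rule"),
            inherits(kap_fg, "hydrophobic_rule"),
            inherits(repulsion, "repulsive_rule"))
  structure(list(fg_fg = fg_fg, kap_fg = kap_fg, repulsion = repulsion),
            class = "interaction_rules")
}
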