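# Reduced-unit system: energy in kT at the simulation temperature, length in
# nm, time in units of 0.1 ns. All engine quantities use these units; helpers
# here convert to/from SI and the units used in the literature (um^2/s for
# diffusion, cP for viscosity, kPa for elastic moduli).

.kB <- 1.380649e-23 # J/K

#' Simulation time unit in seconds (0.1 ns)
#' @export
TIME_UNIT_S <- 1e-10

#' Thermal energy in joules
#'
#' @param temperature_K absolute temperature in kelvin. The model default is
#'   310 K (the unique choice under which the tabulated diffusion
#'   coefficients match kT/(6 pi eta R) at 5 cP).
#' @return kT in joules.
#' @export
kT_joules <- function(temperature_K = 310) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  .kB * temperature_K
}

#' Stokes drag coefficient of a sphere
#'
#' zeta = 6 pi eta R, the free-draining drag used for every bead.
#'
#' @param radius_nm sphere radius in nm.
#' @param viscosity_cP solvent viscosity in centipoise (default 5, the
#'   effective cellular viscosity).
#' @return drag in kg/s.
#' @export
stokes_drag <- function(radius_nm, viscosity_cP = 5) {
  if (any(radius_nm <= 0) || any(viscosity_cP <= 0)) {
    abort("radius and viscosity must be positive", class = "npcbd_domain_error")
  }
  6 * pi * (viscosity_cP * 1e-3) * (radius_nm * 1e-9)
}

#' Diffusion coefficient from drag (fluctuation-dissipation)
#'
#' @param drag_kg_s drag coefficient in kg/s.
#' @param temperature_K temperature in kelvin.
#' @return diffusion coefficient in um^2/s.
#' @export
diffusion_from_drag <- function(drag_kg_s, temperature_K = 310) {
  if (any(drag_kg_s <= 0)) {
    abort("drag must be positive", class = "npcbd_domain_error")
  }
  kT_joules(temperature_K) / drag_kg_s * 1e12 # m^2/s -> um^2/s
}

#' Stokes-Einstein diffusion coefficient of a sphere
#'
#' @inheritParams stokes_drag
#' @inheritParams diffusion_from_drag
#' @return diffusion coefficient in um^2/s.
#' @examples
#' stokes_diffusion(7.5) # ~6.1 um^2/s for a 15 nm cargo-complex
#' @export
stokes_diffusion <- function(radius_nm, viscosity_cP = 5, temperature_K = 310) {
  diffusion_from_drag(stokes_drag(radius_nm, viscosity_cP), temperature_K)
}

#' Convert a diffusion coefficient to reduced units
#'
#' @param D_um2_s diffusion coefficient in um^2/s.
#' @return diffusion coefficient in nm^2 per time unit (0.1 ns).
#' @export
diffusion_to_reduced <- function(D_um2_s) {
  D_um2_s * 1e6 * TIME_UNIT_S # nm^2/s * s/step
}

#' Harmonic spring constant from an elastic modulus
#'
#' k = E A / r0 for a rod of cross-section A and length r0, converted to
#' reduced units. Used to parameterize scaffold bonds and pom springs from
#' the nuclear-envelope elasticity (17 kPa).
#'
#' @param E_kPa Young's modulus in kPa.
#' @param area_nm2 effective cross-sectional area in nm^2.
#' @param r0_nm equilibrium bond length in nm.
#' @param temperature_K temperature in kelvin.
#' @return spring constant in kT/nm^2.
#' @examples
#' spring_constant_from_modulus(17, 100, 10) # ~0.0397 kT/nm^2
#' @export
spring_constant_from_modulus <- function(E_kPa, area_nm2, r0_nm,
                                         temperature_K = 310) {
  if (any(E_kPa <= 0) || any(area_nm2 <= 0) || any(r0_nm <= 0)) {
    abort("modulus, area and bond length must be positive",
          class = "npcbd_domain_error")
  }
  k_N_m <- (E_kPa * 1e3) * (area_nm2 * 1e-18) / (r0_nm * 1e-9)
  k_N_m / (kT_joules(temperature_K) / 1e-18) # (N/m) / (kT/nm^2 in N/m)
}

#' Geometric radius of a lumped protein bead
#'
#' Inverts the sphere-volume formula at the average protein density; the
#' hydrodynamic radius is taken equal to this geometric radius.
#'
#' @param mass_kg lumped mass in kg.
#' @param density_g_cm3 protein density in g/cm^3 (default 1.35).
#' @return radius in nm.
#' @export
lumped_bead_radius <- function(mass_kg, density_g_cm3 = 1.35) {
  if (any(mass_kg <= 0) || any(density_g_cm3 <= 0)) {
    abort("mass and density must be positive", class = "npcbd_domain_error")
  }
  V_m3 <- mass_kg / (density_g_cm3 * 1e3)
  (3 * V_m3 / (4 * pi))^(1 / 3) * 1e9
}

#' Lumped mass of a bead of given radius
#'
#' @param radius_nm bead radius in nm.
#' @inheritParams lumped_bead_radius
#' @return mass in kg.
#' @export
bead_mass_from_radius <- function(radius_nm, density_g_cm3 = 1.35) {
  if (any(radius_nm <= 0) || any(density_g_cm3 <= 0)) {
    abort("radius and density must be positive", class = "npcbd_domain_error")
  }
  (density_g_cm3 * 1e3) * 4 / 3 * pi * (radius_nm * 1e-9)^3
}

#' Bending constant of a discrete wormlike chain
#'
#' k_theta = kT l_p / L_s, the standard relation tying the discrete-WLC
#' bending stiffness to the persistence length.
#'
#' @param l_p persistence length in nm.
#' @param L_s segment contour length in nm.
#' @return bending constant in kT.
#' @examples
#' wlc_bending_constant(0.43, 10) # 0.043 kT
#' @export
wlc_bending_constant <- function(l_p, L_s) {
  if (any(l_p <= 0) || any(L_s <= 0)) {
    abort("persistence and contour length must be positive",
          class = "npcbd_domain_error")
  }
  l_p / L_s
}

#' Convert simulation steps to milliseconds
#' @param steps step count.
#' @param dt time step in reduced units (default 1 = 0.1 ns).
#' @return elapsed time in ms.
#' @export
steps_to_ms <- function(steps, dt = 1) steps * dt * TIME_UNIT_S * 1e3
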