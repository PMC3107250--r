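# Parameterization in reduced units: Stokes drag/diffusion, elastic-modulus
# conversion, lumped bead geometry, WLC bending constant.

test_that("Stokes-Einstein diffusion reproduces the tabulated coefficients", {
  # cargo radii 4.5 / 7.5 / 10 nm and the 0.9 nm FG bead, at 5 cP, 310 K
  expect_equal(stokes_diffusion(4.5), 10.0, tolerance = 0.01)
  expect_equal(stokes_diffusion(7.5), 6.1, tolerance = 0.01)
  expect_equal(stokes_diffusion(10), 4.5, tolerance = 0.01)
  expect_equal(stokes_diffusion(0.9), 50, tolerance = 0.011)
  # fluctuation-dissipation identity D * zeta = kT, any radius
  r <- c(0.5, 0.9, 3, 7.5, 12)
  expect_equal(stokes_diffusion(r) * 1e-12 * stokes_drag(r),
               rep(kT_joules(310), length(r)))
  expect_error(stokes_drag(-1), class = "npcbd_domain_error")
})

test_that("spring constant from Young's modulus converts units correctly", {
  k <- spring_constant_from_modulus(17, 100, 10)
  expect_equal(k, 0.0397, tolerance = 1e-3)
  # k ~ 1/r0
  expect_equal(spring_constant_from_modulus(17, 100, 20), k / 2)
  expect_error(spring_constant_from_modulus(0, 100, 10),
               class = "npcbd_domain_error")
})

test_that("lumped bead radius inverts the sphere-volume formula", {
  expect_equal(lumped_bead_radius(5.65e-24, 1.35), 1.0, tolerance = 0.01)
  m <- 3e-24
  expect_equal(lumped_bead_radius(8 * m), 2 * lumped_bead_radius(m))
  # round trip, and the FG-bead radius reproduces the tabulated D = 50
  m09 <- bead_mass_from_radius(0.9)
  expect_equal(lumped_bead_radius(m09), 0.9)
  expect_equal(stokes_diffusion(lumped_bead_radius(m09)), 50,
               tolerance = 0.011)
  expect_error(lumped_bead_radius(-1e-24), class = "npcbd_domain_error")
})

test_that("discrete-WLC bending constant is kT l_p / L_s", {
  expect_equal(wlc_bending_constant(0.43, 10), 0.043)
  expect_equal(wlc_bending_constant(5, 5), 1)
  expect_equal(wlc_bending_constant(0.43, 5),
               2 * wlc_bending_constant(0.43, 10))
  expect_error(wlc_bending_constant(0, 10), class = "npcbd_domain_error")
})

test_that("time conversion: 1e7 reduced steps is one millisecond", {
  expect_equal(steps_to_ms(1e7), 1)
  expect_equal(steps_to_ms(5e6, dt = 2), 1)
})
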