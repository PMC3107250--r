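# The five potentials: frozen values, limits, and force = -dE/dr by
# central differences over randomized inputs.

test_that("harmonic spring: equilibrium, frozen value, exact gradient", {
  expect_equal(harmonic(5, 2, 5)$energy, 0)
  expect_equal(harmonic(5, 2, 5)$force, 0)
  h <- harmonic(6, 2, 5) # k = 2, stretch 1
  expect_equal(h$energy, 1)
  expect_equal(abs(h$force), 2)
  expect_lt(h$force, 0) # attractive when stretched
  set.seed(42)
  for (i in 1:20) {
    k <- runif(1, 0.01, 50); r0 <- runif(1, 1, 20); r <- runif(1, 0.1, 40)
    expect_equal(harmonic(r, k, r0)$force,
                 -num_deriv(function(x) harmonic(x, k, r0)$energy, r),
                 tolerance = 1e-6)
  }
})

test_that("cosine bending: equilibrium, 1-cos form, harmonic limit", {
  expect_equal(cosine_bending(1.2, 100, 1.2)$energy, 0)
  # full reversal under the 1 - cos form with the scaffold constant
  expect_equal(cosine_bending(pi, 100, 0)$energy, 200)
  # small-deflection Taylor limit
  th0 <- 2
  for (d in c(0.02, 0.05, 0.1)) {
    e <- cosine_bending(th0 + d, 100, th0)$energy
    expect_lt(abs(e - 0.5 * 100 * d^2) / e, 1e-3)
  }
  # torque = -dE/dtheta
  set.seed(43)
  for (i in 1:20) {
    k <- runif(1, 0.01, 100); t0 <- runif(1, 0.3, pi); th <- runif(1, 0.1, pi - 0.1)
    expect_equal(cosine_bending(th, k, t0)$torque,
                 -num_deriv(function(x) cosine_bending(x, k, t0)$energy, th),
                 tolerance = 1e-6)
  }
})

test_that("Marko-Siggia WLC force: zero, midpoint, divergence, domain", {
  expect_equal(wlc_force(0, 10, 0.43), 0)
  expect_equal(wlc_force(5, 10, 0.43), (1 / 0.43) * (1 - 0.25 + 0.5),
               tolerance = 1e-12) # 2.907 kT/nm
  x <- seq(0.5, 9.9, by = 0.1)
  f <- wlc_force(x, 10, 0.43)
  expect_true(all(diff(f) > 0)) # monotone
  expect_gt(wlc_force(9.99, 10, 0.43), 1000) # diverging near contour
  expect_error(wlc_force(10, 10, 0.43), class = "npcbd_extensibility_error")
})

test_that("hydrophobic attraction: cutoff, frozen value, kap > FG-FG", {
  kap <- hydrophobic_rule(2, 1.5)
  ff <- hydrophobic_rule(1.5, 1.0)
  expect_equal(hydrophobic(c(10, 12), kap)$energy, c(0, 0))
  expect_equal(hydrophobic(0, kap)$energy, -2 + 2 * exp(-10 / 1.5),
               tolerance = 1e-12) # about -1.997 kT
  r <- seq(0, 9.99, by = 0.01)
  expect_true(all(abs(hydrophobic(r, kap)$energy) >
                    abs(hydrophobic(r, ff)$energy)))
  expect_true(all(hydrophobic(r, kap)$force < 0)) # attractive inside cutoff
  # continuity at the cutoff
  expect_lt(abs(hydrophobic(10 - 1e-8, kap)$energy), 1e-7)
  # force = -dE/dr away from the cutoff
  set.seed(44)
  for (i in 1:20) {
    rule <- hydrophobic_rule(runif(1, 1.5, 10), runif(1, 1, 2))
    rr <- runif(1, 0.1, 9)
    expect_equal(hydrophobic(rr, rule)$force,
                 -num_deriv(function(x) hydrophobic(x, rule)$energy, rr),
                 tolerance = 1e-6)
  }
})

test_that("soft repulsion: cutoff, finite at contact, monotone, gradient", {
  rep_rule <- repulsive_rule()
  expect_equal(soft_repulsive(c(1.35, 2), rep_rule)$energy, c(0, 0))
  e0 <- soft_repulsive(0, rep_rule)$energy
  expect_equal(e0, 100 * (1 - exp(-1.35)), tolerance = 1e-12) # ~74.1 kT
  expect_true(is.finite(e0))
  r <- seq(0, 2, by = 0.01)
  expect_true(all(diff(soft_repulsive(r, rep_rule)$energy) <= 0))
  set.seed(45)
  for (i in 1:20) {
    rr <- runif(1, 0.05, 1.2)
    expect_equal(soft_repulsive(rr, rep_rule)$force,
                 -num_deriv(function(x) soft_repulsive(x, rep_rule)$energy, rr),
                 tolerance = 1e-6)
  }
})

test_that("interaction rule set carries the model defaults", {
  rules <- interaction_rules()
  expect_equal(rules$kap_fg$epsilon, 2)
  expect_equal(rules$kap_fg$xi, 1.5)
  expect_equal(rules$fg_fg$epsilon, 1.5)
  expect_equal(rules$fg_fg$xi, 1)
  expect_equal(rules$fg_fg$cutoff, 10)
  expect_equal(rules$repulsion$epsilon_rep, 100)
  expect_equal(rules$repulsion$sigma, 1)
  expect_equal(rules$repulsion$cutoff, 1.35)
})
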