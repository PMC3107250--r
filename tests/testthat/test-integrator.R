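# Overdamped Langevin integration: noise scaling, deterministic drift,
# Boltzmann sampling, free diffusion, finite-extensibility rejection,
# reproducibility.

test_that("Brownian displacements have variance 2 D dt per component", {
  set.seed(1)
  d <- brownian_displacement(50, dt = 1, n = 2e5)
  expect_lt(abs(mean(d)), 4 * 0.1 / sqrt(4e5))
  expect_lt(abs(var(c(d)) - 0.01), 4 * 0.01 * sqrt(2 / 4e5))
  set.seed(99); a <- brownian_displacement(50, n = 10)
  set.seed(99); b <- brownian_displacement(50, n = 10)
  expect_identical(a, b)
})

test_that("bd_step: no force and no noise leaves positions unchanged; a
           constant force gives displacement F D dt", {
  pos <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  D <- c(50, 50); mob <- c(TRUE, FALSE)
  same <- bd_step(pos, matrix(0, 2, 2), D, mob)
  expect_identical(same, pos)
  f <- matrix(c(2, -1, 5, 5), 2, 2, byrow = TRUE)
  stepped <- bd_step(pos, f, D, mob)
  expect_equal(stepped[1, ], pos[1, ] + c(2, -1) * diffusion_to_reduced(50))
  expect_equal(stepped[2, ], pos[2, ]) # immobile bead pinned
})

test_that("the engine's deterministic drift matches the R reference step", {
  hw <- make_fixture("harmonic_well")
  st <- hw$structure
  cfg <- integrator_config(n_steps = 1, seed = 1, noise = FALSE,
                           sample_every = 1)
  r <- run_simulation(st, config = cfg, wall_on = FALSE, detect = FALSE)
  f <- total_forces(st)$forces
  ref <- bd_step(cbind(st$beads$x, st$beads$y), cbind(f$fx, f$fy),
                 st$beads$diffusion, st$beads$mobile)
  expect_equal(r$positions, ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a bead in a harmonic well samples variance kT/k per dimension", {
  hw <- make_fixture("harmonic_well") # k = 1 kT/nm^2 -> variance 1 nm^2
  cfg <- integrator_config(n_steps = 1e6, seed = 3, sample_every = 50)
  r <- run_simulation(hw$structure, config = cfg, wall_on = FALSE,
                      detect = FALSE, track_bead = 2L)
  xs <- r$track$x[r$track$step > 2e5]
  ys <- r$track$y[r$track$step > 2e5]
  expect_equal(var(xs), 1, tolerance = 0.05)
  expect_equal(var(ys), 1, tolerance = 0.05)
  expect_equal(mean(xs), 0, tolerance = 0.05)
})

test_that("free-bead MSD reproduces 4 D t within 3 standard errors", {
  fx <- make_fixture("free_bead")
  D <- fx$structure$beads$diffusion[1]
  nrep <- 60; nstep <- 2000
  msd <- vapply(seq_len(nrep), function(i) {
    cfg <- integrator_config(n_steps = nstep, seed = 1000 + i,
                             sample_every = nstep)
    r <- run_simulation(fx$structure, config = cfg, wall_on = FALSE,
                        detect = FALSE)
    sum(r$positions[1, ]^2)
  }, numeric(1))
  expected <- 4 * diffusion_to_reduced(D) * nstep
  # each squared displacement is exponential with mean 4Dt (2D), SE = mean/sqrt(n)
  expect_lt(abs(mean(msd) - expected), 3 * expected / sqrt(nrep))
})

test_that("WLC extension never reaches f_max L_s in a long tethered run", {
  ch <- make_fixture("single_wlc_chain")
  cfg <- integrator_config(n_steps = 2e5, seed = 4, sample_every = 1e3)
  r <- run_simulation(ch$structure, config = cfg, wall_on = FALSE,
                      detect = FALSE, track_bead = 6L)
  expect_lt(r$counters$max_wlc_ratio, 0.99)
})

test_that("rejection reverts a separating move near the contour length", {
  # two-bead segment pre-stretched to 0.985 L_s, threshold f_max = 0.99:
  # with noise the run must never cross the threshold
  ch <- make_fixture("single_wlc_chain", overrides = list(n_segments = 1))
  ch$structure$beads$x[2] <- 9.85
  cfg <- integrator_config(n_steps = 2e4, seed = 5, sample_every = 100)
  r <- run_simulation(ch$structure, config = cfg, wall_on = FALSE,
                      detect = FALSE, track_bead = 2L)
  expect_lt(r$counters$max_wlc_ratio, 0.99)
})

test_that("zero-step runs return the initial state only", {
  hw <- make_fixture("harmonic_well")
  cfg <- integrator_config(n_steps = 0, seed = 1, sample_every = 1)
  r <- run_simulation(hw$structure, config = cfg, wall_on = FALSE,
                      detect = FALSE, track_bead = 2L)
  expect_equal(r$counters$steps_run, 0)
  expect_equal(r$positions[2, ], c(1, 0), ignore_attr = TRUE)
})

test_that("identical (config, seed) gives bit-identical trajectories", {
  fx <- make_fixture("mini_npc", overrides = list(
    fg_total_motifs = 48, fg_region_weights = c(3, 2, 3)))
  cfg <- integrator_config(n_steps = 5e3, seed = 11, sample_every = 100)
  r1 <- run_simulation(fx$structure, config = cfg, detect = FALSE,
                       track_bead = 3L)
  r2 <- run_simulation(fx$structure, config = cfg, detect = FALSE,
                       track_bead = 3L)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$track, r2$track)
})

test_that("beads never cross the rigid nuclear envelope", {
  fx <- make_fixture("mini_npc", overrides = list(
    fg_total_motifs = 48, fg_region_weights = c(3, 2, 3)))
  st <- fx$structure
  cfg <- integrator_config(n_steps = 2e4, seed = 12, sample_every = 1e4)
  r <- run_simulation(st, config = cfg, detect = FALSE)
  w <- st$wall
  inside_wall <- r$positions[, 2] >= w$y_lo & r$positions[, 2] <= w$y_hi &
    abs(r$positions[, 1]) >= wall_radius(r$positions[, 2], st$config) +
      w$margin
  inside_wall[!st$beads$mobile] <- FALSE # anchors live in the envelope
  expect_false(any(inside_wall))
})
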