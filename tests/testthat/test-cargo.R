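# Cargo-complex construction, placement, and transport-event bookkeeping.

test_that("binding spots span a semicircular arc with equal spacing", {
  cg <- make_cargo(15, 8)
  expect_equal(cg$n_binding_spots, 8L)
  expect_true(cg$active)
  ang <- atan2(cg$spot_offsets[, 2], cg$spot_offsets[, 1])
  gaps <- diff(sort(ang)) * 180 / pi
  expect_equal(gaps, rep(180 / 7, 7))
  # spots lie on the surface
  expect_equal(sqrt(rowSums(cg$spot_offsets^2)), rep(7.5, 8))
})

test_that("a spotless cargo is inert but keeps its hydrodynamics", {
  cg <- make_cargo(15, 0)
  expect_false(cg$active)
  expect_equal(nrow(cg$spot_offsets), 0)
  expect_equal(cg$diffusion, 6.1, tolerance = 0.01)
  expect_error(make_cargo(-3, 8), class = "npcbd_domain_error")
  expect_error(make_cargo(15, -1), class = "npcbd_domain_error")
})

test_that("entry placement is axial, deterministic, outside the kap cutoff", {
  st <- build_npc(seed = 1)
  cg <- make_cargo(15, 8)
  p1 <- place_cargo_at_entry(st, cg)
  p2 <- place_cargo_at_entry(st, cg)
  expect_identical(p1, p2)
  expect_equal(p1[1], 0)
  fg <- st$beads[st$beads$group %in% c("fg_central", "fg_peripheral"), ]
  dmin <- min(sqrt((fg$x - p1[1])^2 + (fg$y - p1[2])^2)) - cg$radius
  expect_gt(dmin, 10)
  expect_error(place_cargo_at_entry(st, cg, standoff = -5),
               class = "npcbd_placement_error")
})

test_that("offline event detection finds the first full-loading sample", {
  cg <- make_cargo(15, 8)
  # scripted axial descent: enters the basket window (y <= -57.5) at index 8
  y <- c(30, 20, 10, 0, -20, -40, -50, -55, -60, -70, -80)
  rec <- fab_record(y, engaged = c(0, rep(1, 10)), cargo = cg)
  rec <- detect_events(rec)
  expect_equal(rec$events$t_end_step, 8)
  expect_equal(rec$events$outcome, "completed")
  expect_equal(rec$events$t_start_step, 1) # first engaged sample
  expect_equal(rec$events$fpt_ms, steps_to_ms(7))
})

test_that("a cargo that never approaches stays timed_out", {
  rec <- fab_record(seq(40, 60, length.out = 10), cargo = make_cargo(15, 8))
  rec <- detect_events(rec)
  expect_true(is.na(rec$events$t_end_step))
  expect_equal(rec$events$outcome, "timed_out")
})

test_that("single-run batches report an undefined SEM", {
  fs <- fpt_sample(2.5)
  expect_equal(attr(fs, "n"), 1)
  expect_true(is.na(attr(fs, "sem")))
  fs3 <- fpt_sample(c(1, 2, 3))
  expect_equal(attr(fs3, "mean"), 2)
  expect_equal(attr(fs3, "sem"), sd(1:3) / sqrt(3))
})

test_that("run_batch records per-run outcomes and aggregates completed FPTs", {
  fx <- make_fixture("mini_npc", overrides = list(
    fg_total_motifs = 48, fg_region_weights = c(3, 2, 3)))
  st <- fx$structure
  start <- c(0, st$planes$channel_top + fx$cargo$radius + 2)
  b <- run_batch(st, fx$cargo, n_runs = 2, base_seed = 5,
                 config = integrator_config(n_steps = 2e4,
                                            sample_every = 500),
                 equil_steps = 1e3, cargo_position = start,
                 confine = list(x = 30, ytop = start[2] + 8,
                                ybot = st$planes$exit - 5))
  expect_equal(nrow(b$outcomes), 2)
  expect_true(all(b$outcomes$outcome %in% c("completed", "timed_out")))
  expect_s3_class(b$fpt, "fpt_sample")
})
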