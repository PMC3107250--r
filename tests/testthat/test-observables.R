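# Observables are pure functions of recorded tracks/contacts: radial
# histograms, bond-lifetime episodes, occupancy, shuttles, residence.

test_that("radial histogram: normalization, degenerate and uniform tracks", {
  pl <- default_planes()
  # constant radius: one occupied bin with probability 1
  tr <- tibble::tibble(y = rep(-25, 100), x = rep(17.2, 100), r = 17.2)
  h <- radial_probability(tr, pl)
  expect_equal(sum(h$probability), 1)
  expect_equal(max(h$probability), 1)
  expect_equal(h$r_mid[which.max(h$probability)], 17.5)
  expect_equal(sum(h$count), 100)
  # uniform radial track is flat within multinomial error
  set.seed(7)
  n <- 40000
  tru <- tibble::tibble(y = rep(-25, n), x = runif(n, 0, 20))
  hu <- radial_probability(tru, pl)
  occ <- hu$probability[hu$r_mid < 20]
  expect_lt(max(abs(occ - 1 / 20)), 5 * sqrt((1 / 20) / n))
  # no samples inside the channel -> explicit empty signal
  expect_error(radial_probability(tibble::tibble(y = rep(10, 5), x = 0), pl),
               class = "npcbd_empty_histogram")
})

test_that("bond episodes are maximal runs with lifetime = steps * dt", {
  # single pair, one-step contact: the minimum lifetime is one time step
  # (0.1 ns at dt = 1; 0.01 ns at the finer dt = 0.1 step)
  log1 <- tibble::tibble(step = 5, spot = 1L, motif = 10L)
  expect_equal(bond_lifetimes(log1)$lifetime_ns, 0.1)
  expect_equal(bond_lifetimes(log1, dt = 0.1)$lifetime_ns, 0.01)
  # n consecutive steps -> n steps' worth of lifetime
  logn <- tibble::tibble(step = 0:9, spot = 1L, motif = 10L)
  expect_equal(bond_lifetimes(logn, dt = 0.1)$lifetime_ns, 0.1)
  # scripted on/off pattern: episode count equals the number of on-runs
  on <- c(1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 1)
  logs <- tibble::tibble(step = which(on == 1) - 1, spot = 2L, motif = 3L)
  ep <- bond_lifetimes(logs, dt = 0.1)
  expect_equal(nrow(ep), 4)
  expect_equal(sort(ep$lifetime_ns), sort(c(2, 1, 3, 1) * 0.01))
  # partition property: episodes disjoint and cover exactly the contact steps
  set.seed(8)
  for (rep in 1:5) {
    steps <- sort(sample(0:60, 25))
    lg <- tibble::tibble(step = steps, spot = 1L, motif = 1L)
    epr <- bond_lifetimes(lg)
    covered <- unlist(Map(seq, epr$start, epr$end))
    expect_equal(sort(covered), steps)
    expect_true(all(diff(epr$start) > 0))
  }
})

test_that("occupancy is the conditional mean over engaged steps", {
  # all eight spots engaged at every logged step
  full <- tidyr::expand_grid(step = 0:9, spot = 1:8)
  expect_equal(occupancy(dplyr::mutate(full, motif = spot)), 8)
  # alternating 8/0: only engaged steps enter the log, mean stays 8
  alt <- tidyr::expand_grid(step = seq(0, 8, by = 2), spot = 1:8)
  expect_equal(occupancy(dplyr::mutate(alt, motif = spot)), 8)
  # inert cargo: undefined signal
  rec <- fab_record(c(0, 1), cargo = make_cargo(15, 0))
  expect_error(occupancy(rec), class = "npcbd_undefined_signal")
})

test_that("shuttle counting follows entry/mid crossings", {
  pl <- default_planes()
  mono <- fab_record(seq(30, -120, length.out = 50))
  expect_equal(shuttle_count(mono), 0)
  # cross mid, return past entry, then complete: one round trip
  y1 <- c(20, 5, -10, -26, -10, 5, 15, -5, -30, -60, -120)
  expect_equal(shuttle_count(fab_record(y1)), 1)
  # two round trips
  y2 <- c(10, -30, 10, -26, 5, -40, -120)
  expect_equal(shuttle_count(fab_record(y2)), 2)
  recs <- list(fab_record(y1), mono, fab_record(y2))
  expect_equal(shuttle_percentage(recs), 100 * 2 / 3)
})

test_that("channel residence fraction over the transport window", {
  pl <- default_planes()
  y <- c(30, 10, -10, -20, -30, -40, -60, -80, -100, -125)
  rec <- fab_record(y, events = list(
    t_start_step = 1, t_end_step = 9, outcome = "completed"))
  # window samples 1..9; y in (-50, 0) at indices 3..6 -> 4 of 9
  expect_equal(channel_residence_fraction(rec), 4 / 9)
  # whole window inside the channel
  rec2 <- fab_record(rep(-25, 6), events = list(
    t_start_step = 0, t_end_step = 5, outcome = "completed"))
  expect_equal(channel_residence_fraction(rec2), 1)
  # teleported through: ~0 of the window inside
  rec3 <- fab_record(c(30, -125, -125), events = list(
    t_start_step = 0, t_end_step = 1, outcome = "completed"))
  expect_lt(channel_residence_fraction(rec3), 0.51)
  rec4 <- fab_record(c(30, 20))
  expect_error(channel_residence_fraction(rec4),
               class = "npcbd_undefined_signal")
})

test_that("engine episodes respect the one-step minimum and pass through", {
  fx <- make_fixture("mini_npc", overrides = list(
    fg_total_motifs = 48, fg_region_weights = c(3, 2, 3)))
  st <- fx$structure
  start <- c(0, st$planes$channel_top + fx$cargo$radius)
  cfg <- integrator_config(n_steps = 5e3, seed = 21, sample_every = 100,
                           record_contact_log = TRUE, stop_on_end = FALSE)
  r <- run_simulation(st, fx$cargo, cargo_position = start, config = cfg)
  if (nrow(r$episodes) > 0) {
    expect_true(all(r$episodes$lifetime_ns >= 0.01))
    # engine episodes match an offline run-length encoding of the log
    off <- bond_lifetimes(r$contact_log)
    eng <- dplyr::arrange(r$episodes, start, spot, motif)
    off <- dplyr::arrange(off, start, spot, motif)
    expect_equal(nrow(eng), nrow(off))
    expect_equal(eng$lifetime_ns, off$lifetime_ns)
  } else {
    succeed("no contacts formed in this short run")
  }
})
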