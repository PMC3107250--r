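# NPC assembly: motif accounting, span, determinism, stress-free build,
# discretization scaling, filament ablation.

test_that("default build carries 720 FG motifs over a 160 nm span", {
  st <- build_npc(seed = 1)
  expect_equal(count_fg_motifs(st), 720)
  expect_equal(st$config$transport_span, 160)
  expect_equal(st$planes$entry - st$planes$exit, 160)
  expect_true(fg_density_scaled(st) >= 2700 && fg_density_scaled(st) <= 3000)
  expect_equal(sum(lengths(st$chains$bead_ids)), 720)
  expect_silent(validate_structure(st))
})

test_that("rebuilding with the same seed is identical, different seed is not", {
  a <- build_npc(seed = 7)
  b <- build_npc(seed = 7)
  expect_identical(a$beads, b$beads)
  expect_identical(a$wlc, b$wlc)
  d <- build_npc(seed = 8)
  expect_false(isTRUE(all.equal(a$beads$x, d$beads$x)))
})

test_that("the as-built scaffold is stress-free (zero net force, no noise)", {
  st0 <- build_scaffold()
  f <- total_forces(st0)
  expect_lt(max(abs(c(f$forces$fx, f$forces$fy))), 1e-9)
})

test_that("halving the bead spacing doubles scaffold beads, not FG motifs", {
  st10 <- build_npc(seed = 1)
  st5 <- build_npc(geometry_config(scaffold_bead_spacing = 5), seed = 1)
  n10 <- sum(st10$beads$group == "scaffold")
  n5 <- sum(st5$beads$group == "scaffold")
  expect_gt(n5 / n10, 1.7)
  expect_lt(n5 / n10, 2.3)
  expect_equal(count_fg_motifs(st5), 720)
})

test_that("configuration errors are informative", {
  expect_error(geometry_config(scaffold_bead_spacing = 60),
               class = "npcbd_config_error")
  expect_error(geometry_config(fg_segment_length = 2),
               class = "npcbd_config_error")
  expect_error(geometry_config(n_spokes = 8), class = "npcbd_config_error")
  # unplaceable motif budget reports the achievable count
  err <- tryCatch(build_npc(geometry_config(fg_total_motifs = 700), seed = 1),
                  error = function(e) e)
  expect_s3_class(err, "npcbd_config_error")
  expect_match(conditionMessage(err), "achievable")
})

test_that("hourglass profile has its waist at mid-channel", {
  cfg <- geometry_config()
  expect_equal(wall_radius(-25, cfg), 25)
  expect_equal(wall_radius(0, cfg), 35)
  expect_equal(wall_radius(-50, cfg), 35)
})

test_that("Stokes consistency holds for every bead in the table", {
  st <- build_npc(seed = 2)
  mob <- st$beads[st$beads$mobile, ]
  expect_equal(mob$diffusion * 1e-12 * mob$drag,
               rep(kT_joules(310), nrow(mob)))
})

test_that("filament deletion removes exactly the filament-grafted set", {
  st <- build_npc(seed = 3)
  fil_chain_ids <- st$chains$chain_id[st$chains$region == "filament"]
  n_fil_motifs <- sum(lengths(st$chains$bead_ids[
    st$chains$chain_id %in% fil_chain_ids]))
  n_fil_scaffold <- sum(st$beads$region == "filament" &
                          st$beads$group == "scaffold")
  ab <- delete_cytoplasmic_filaments(st)
  expect_equal(count_fg_motifs(ab), 720 - n_fil_motifs)
  expect_equal(nrow(ab$beads),
               nrow(st$beads) - n_fil_motifs - n_fil_scaffold)
  # channel and basket untouched
  for (reg in c("channel", "basket")) {
    expect_equal(sum(ab$beads$region == reg & ab$beads$group == "scaffold"),
                 sum(st$beads$region == reg & st$beads$group == "scaffold"))
  }
  expect_false(any(ab$chains$region == "filament"))
  expect_silent(validate_structure(ab))
  # ids remain contiguous and force evaluation still works
  expect_equal(ab$beads$id, seq_len(nrow(ab$beads)))
  f <- total_forces(ab)
  expect_true(all(is.finite(c(f$forces$fx, f$forces$fy))))
  expect_warning(delete_cytoplasmic_filaments(ab), "no cytoplasmic filaments")
})
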