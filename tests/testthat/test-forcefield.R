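# Assembled force evaluation: action-reaction, neighbor-list equivalence,
# interaction-rule asymmetries, and force = -grad(E) for the full system.

test_that("internal forces sum to zero over all beads (action-reaction)", {
  st <- tiny_npc(seed = 2)
  f <- total_forces(st)$forces
  expect_lt(abs(sum(f$fx)), 1e-10)
  expect_lt(abs(sum(f$fy)), 1e-10)
  cargo <- make_cargo(15, 8)
  f2 <- total_forces(st, cargo, c(0, 10))$forces
  expect_lt(abs(sum(f2$fx)), 1e-10)
  expect_lt(abs(sum(f2$fy)), 1e-10)
})

test_that("neighbor-list and brute-force O(N^2) evaluation agree to 1e-10", {
  st <- tiny_npc(seed = 4)
  cargo <- make_cargo(15, 8)
  pos <- c(0, 5) # near the mouth so kap-FG terms are active
  brute <- total_forces(st, cargo, pos, neighbor_list = FALSE)
  nl <- total_forces(st, cargo, pos, neighbor_list = TRUE)
  expect_lt(max(abs(brute$forces$fx - nl$forces$fx)), 1e-10)
  expect_lt(max(abs(brute$forces$fy - nl$forces$fy)), 1e-10)
  expect_equal(brute$energy, nl$energy, tolerance = 1e-12)
})

test_that("an isolated bead feels no force", {
  fx <- make_fixture("free_bead")
  f <- total_forces(fx$structure)$forces
  expect_equal(unlist(f[1, c("fx", "fy")]), c(fx = 0, fy = 0))
})

test_that("inert cargo zeroes kap-FG terms and leaves FG-FG untouched", {
  st <- tiny_npc(seed = 5)
  pos <- c(0, 2)
  act <- total_forces(st, make_cargo(15, 8), pos)$energy
  inert <- total_forces(st, make_cargo(15, 0), pos)$energy
  expect_lt(act[["hydrophobic_kap_fg"]], 0) # engaged at the mouth
  expect_equal(inert[["hydrophobic_kap_fg"]], 0)
  expect_equal(inert[["hydrophobic_fg_fg"]], act[["hydrophobic_fg_fg"]])
})

test_that("peripheral FG beads contribute no FG-FG hydrophobic energy", {
  ch <- make_fixture("single_wlc_chain")
  # coil the chain so non-bonded bead pairs sit inside the 10 nm cutoff
  ch$structure$beads$x <- c(0, 4, 8, 4, 8, 4)
  ch$structure$beads$y <- c(0, 3, 6, 9, 12, 15)
  central <- total_forces(ch$structure)$energy
  expect_lt(central[["hydrophobic_fg_fg"]], 0) # central chain coheres
  per <- ch$structure
  per$beads$group[per$beads$group == "fg_central"] <- "fg_peripheral"
  peri <- total_forces(per)$energy
  expect_equal(peri[["hydrophobic_fg_fg"]], 0)
  # bonded terms unaffected by the cohesion flag
  expect_equal(peri[["wlc"]], central[["wlc"]])
})

test_that("total force is -grad of total energy (central differences)", {
  st <- tiny_npc(seed = 6)
  cargo <- make_cargo(15, 8)
  cpos <- c(0, 5)
  pos0 <- cbind(st$beads$x, st$beads$y)
  f <- total_forces(st, cargo, cpos)$forces
  h <- 1e-5
  set.seed(9)
  picks <- sample(which(st$beads$mobile), 12)
  for (i in picks) {
    for (d in 1:2) {
      pp <- pos0; pp[i, d] <- pp[i, d] + h
      pm <- pos0; pm[i, d] <- pm[i, d] - h
      g <- (total_energy_at(st, pp, cargo, cpos) -
              total_energy_at(st, pm, cargo, cpos)) / (2 * h)
      fi <- if (d == 1) f$fx[i] else f$fy[i]
      expect_equal(fi, -g, tolerance = 1e-4)
    }
  }
})
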