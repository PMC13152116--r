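test_that("read_trajectory handles multi-model, single-model and mismatches", {
  b <- bundle_fixture()
  p <- tempfile(fileext = ".pdb")
  make_rigid_trajectory(b$structure, n_frames = 5, path = p)
  tr <- read_trajectory(p)
  expect_equal(tr$n_frames, 5L)
  expect_equal(nrow(tr$atoms), nrow(b$structure$atoms))

  single <- tempfile(fileext = ".pdb")
  write_structure(b$structure, single)
  expect_warning(tr1 <- read_trajectory(single), "single-model")
  expect_equal(tr1$n_frames, 1L)

  bad <- tempfile(fileext = ".pdb")
  lines <- readLines(p)
  ends <- which(startsWith(lines, "ENDMDL"))
  writeLines(lines[-(ends[1] - 1L)], bad)  # drop one atom from model 1
  expect_error(read_trajectory(bad), "inconsistent atom counts")
})

test_that("site_occupancy marks sites by radius with single counting", {
  sites <- data.frame(name = c("s1", "s2"), x = c(0, 10), y = 0, z = 0)
  atoms <- data.frame(name = "O", element = "O", chain = "W",
                      resno = 1:2, resname = "HOH", record_class = "water",
                      x = c(0, 1.6), y = 0, z = 0)
  st <- as_hydronet_structure(atoms)
  tr <- make_rigid_trajectory(st, n_frames = 3)
  occ <- site_occupancy(tr, sites, radius = 1.5, superpose = FALSE)
  expect_true(all(occ$occupied[, "s1"]))
  expect_false(any(occ$occupied[, "s2"]))

  # water exactly at radius + 0.1 -> unoccupied
  st2 <- st; st2$atoms$x <- c(1.6, 30)
  occ2 <- site_occupancy(make_rigid_trajectory(st2, n_frames = 2), sites,
                         radius = 1.5, superpose = FALSE)
  expect_false(any(occ2$occupied[, "s1"]))

  # two waters in one site in one frame: occupied once, event logged
  st3 <- st; st3$atoms$x <- c(0.3, -0.3)
  expect_message(
    occ3 <- site_occupancy(make_rigid_trajectory(st3, n_frames = 2), sites,
                           radius = 1.5, superpose = FALSE),
    "counted once")
  expect_equal(attr(occ3, "multiplicity_events"), 2L)
  expect_equal(as.integer(nwat_series(occ3)), c(1L, 1L))

  expect_error(site_occupancy(make_rigid_trajectory(
    as_hydronet_structure(atoms[0, ]), n_frames = 1), sites), "no water|empty")
})

test_that("nwat_series row sums and threshold fraction", {
  m <- matrix(TRUE, 4, 9)
  occ <- occupancy_from_matrix(m, dt = 10)
  nw <- nwat_series(occ)
  expect_equal(as.integer(nw), rep(9L, 4))
  expect_equal(attr(nw, "frac_at_threshold"), 1)

  expect_equal(as.integer(nwat_series(occupancy_from_matrix(
    matrix(FALSE, 4, 9), dt = 10))), rep(0L, 4))

  checker <- occupancy_from_matrix(
    matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2), dt = 10)
  expect_equal(as.integer(nwat_series(checker)), c(1L, 1L))
})

test_that("N_Wat never decreases when the assignment radius grows", {
  set.seed(77)
  sites <- data.frame(name = paste0("s", 1:4),
                      x = runif(4, 0, 10), y = runif(4, 0, 10),
                      z = runif(4, 0, 10))
  atoms <- data.frame(name = "O", element = "O", chain = "W", resno = 1:6,
                      resname = "HOH", record_class = "water",
                      x = runif(6, 0, 10), y = runif(6, 0, 10),
                      z = runif(6, 0, 10))
  tr <- make_rigid_trajectory(as_hydronet_structure(atoms),
                              n_frames = 10, sigma = 1.5, seed = 3)
  prev <- NULL
  for (r in c(0.8, 1.5, 2.5, 4)) {
    nw <- as.integer(nwat_series(site_occupancy(tr, sites, radius = r,
                                                superpose = FALSE)))
    if (!is.null(prev)) expect_true(all(nw >= prev))
    prev <- nw
  }
})

test_that("rehydration_time definition, first passage and sustain window", {
  nw <- c(rep(0L, 99), rep(9L, 50))
  expect_equal(rehydration_time(nw, 9, sustain_frames = 10, dt = 100), 10)
  expect_true(is.na(rehydration_time(rep(5L, 100), 9, 10, dt = 100)))
  # one-frame spike at frame 10, sustained block from frame 40
  nw2 <- rep(0L, 60); nw2[10] <- 9L; nw2[40:60] <- 9L
  expect_equal(rehydration_time(nw2, 9, sustain_frames = 5, dt = 100),
               40 * 100 / 1000)
  # sustain 1 equals first passage
  expect_equal(rehydration_time(nw2, 9, sustain_frames = 1, dt = 100),
               10 * 100 / 1000)
})

test_that("hbond_lifetime: episode enumeration, bridging, undefined", {
  lt <- hbond_lifetime(c(1, 1, 1, 0, 0, 1, 1), dt = 10)
  expect_equal(sort(lt$episodes), c(20, 30))
  expect_equal(lt$t_avg, 25)
  expect_equal(lt$n_hbond, 2L)
  expect_equal(lt$censored_n, 2L)  # both episodes touch the boundaries

  lt2 <- hbond_lifetime(c(1, 1, 1, 0, 0, 1, 1), dt = 10,
                        bridge_tolerance_frames = 2)
  expect_equal(lt2$n_hbond, 1L)
  expect_equal(lt2$t_avg, 70)

  # all frames bonded over 1 ns
  lt3 <- hbond_lifetime(rep(1, 100), dt = 10)
  expect_equal(lt3$n_hbond, 1L)
  expect_equal(lt3$t_avg, 1000)

  lt4 <- hbond_lifetime(rep(0, 50), dt = 10)
  expect_true(lt4$undefined)
  expect_equal(lt4$n_hbond, 0L)

  # leading/trailing gaps are never bridged into episodes
  lt5 <- hbond_lifetime(c(0, 1, 1, 0), dt = 10, bridge_tolerance_frames = 5)
  expect_equal(lt5$n_hbond, 1L)
  expect_equal(lt5$t_avg, 20)
})

test_that("t_avg invariant to padding with unbonded frames", {
  set.seed(8)
  p <- as.integer(runif(500) < 0.4)
  a <- hbond_lifetime(c(rep(0, 25), p, rep(0, 30)), dt = 10)
  b <- hbond_lifetime(p, dt = 10)
  expect_equal(a$t_avg, b$t_avg)
  expect_equal(a$n_hbond, b$n_hbond)
})

test_that("episode multiset is additive over gap-separated concatenation", {
  set.seed(9)
  p1 <- as.integer(runif(300) < 0.5)
  p2 <- as.integer(runif(300) < 0.5)
  joint <- hbond_lifetime(c(p1, 0L, p2), dt = 10)
  sep <- c(hbond_lifetime(p1, 10)$episodes, hbond_lifetime(p2, 10)$episodes)
  expect_equal(sort(joint$episodes), sort(sep))
})

test_that("two-state estimator converges for tau_b >> dt (bias < 5%)", {
  tr <- make_occupancy_trajectory(tau_b = 1340, tau_u = 500, dt = 10,
                                  n_frames = 1e5, n_sites = 3, seed = 42)
  occ <- occupancy_from_matrix(tr$presence, tr$dt)
  pooled <- attr(occupancy_lifetimes(occ), "pooled")
  expect_lt(abs(pooled$t_avg_ps - 1340) / 1340, 0.05)
})

test_that("lifetime_table reports observed pairs from coordinates", {
  b <- bundle_fixture()
  tr <- make_rigid_trajectory(b$structure, n_frames = 4)
  sites <- cbind(b$sites, region = c(rep("S", 8), "G"))
  tab <- lifetime_table(tr, sites, b$structure, superpose = FALSE)
  expect_true(nrow(tab) > 0)
  # the persistent fixture bonds span the whole trajectory
  expect_true(all(tab$t_avg_ns == 4 * tr$dt / 1000))
  expect_true(all(tab$n_hbond == 1L))
  # intended pair present: W_S1 coordinated by D2.50's carboxylate
  expect_true(any(tab$site == "W_S1" & grepl("^A/65/", tab$residue_atom)))
  # absent pair: ligand-pocket contacts are not in the site list
  expect_false(any(grepl("W_L", tab$site)))
})

test_that("comparative mode pairs columns and signs the difference", {
  fast <- make_occupancy_trajectory(200, 300, 10, 2e4, 3, seed = 1)
  slow <- make_occupancy_trajectory(1000, 300, 10, 2e4, 3, seed = 2)
  ta <- occupancy_lifetimes(occupancy_from_matrix(slow$presence, 10))
  tb <- occupancy_lifetimes(occupancy_from_matrix(fast$presence, 10))
  cmp <- compare_lifetimes(ta, tb, labels = c("Gs", "Gi"))
  expect_true(all(c("t_avg_ns_Gs", "t_avg_ns_Gi") %in% names(cmp)))
  expect_true(all(cmp$delta_t_avg_ns > 0))
})
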