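test_that("shell counts respect the closed 3.4 / 5.0 boundaries", {
  pos <- array(NA_real_, c(3, 3, 1))
  pos[1, , 1] <- c(0, 3.0, 0)    # first shell
  pos[2, , 1] <- c(0, 4.5, 0)    # second shell
  pos[3, , 1] <- c(0, 3.4, 0)    # exactly r1: first shell (closed bound)
  traj <- script_traj(pos)
  sh <- shell_counts(traj, select_atoms(traj$topology, "ligand", resname = "LIG"))
  expect_equal(sh$first, 2L)
  expect_equal(sh$second, 1L)
})

test_that("scripted shell membership is recovered frame by frame", {
  set.seed(41)
  nf <- 20
  dists <- matrix(sample(c(2.5, 4.2, 8), 3 * nf, replace = TRUE), 3, nf)
  pos <- array(NA_real_, c(3, 3, nf))
  for (w in 1:3) for (f in 1:nf) pos[w, , f] <- c(0, dists[w, f], 0)
  traj <- script_traj(pos)
  sh <- shell_counts(traj, select_atoms(traj$topology, "ligand", resname = "LIG"))
  expect_equal(sh$first, colSums(dists <= 3.4))
  expect_equal(sh$second, colSums(dists > 3.4 & dists <= 5))
  expect_equal(sh$mean_first, mean(colSums(dists <= 3.4)))
  # conservation: first + second equals the within-r2 count on every frame
  expect_equal(sh$first + sh$second, colSums(dists <= 5))
})

test_that("contact occupancy is definitional and ordered", {
  nf <- 100
  pos <- array(NA_real_, c(2, 3, nf))
  near <- c(0, 3, 0)
  away <- c(0, 40, 0)
  for (f in 1:nf) {
    pos[1, , f] <- if (f <= 50) near else away   # 50% at ligand
    pos[2, , f] <- away + c(10, 0, 0)            # never within cutoff
  }
  traj <- script_traj(pos)
  occ <- hbond_occupancy(traj, select_atoms(traj$topology, "ligand", resname = "LIG"))
  expect_equal(unique(occ$acceptor), "WAT501@O")
  expect_equal(occ$occupancy[occ$donor == "LIG@C1"], 50)
  expect_equal(occ$n_frames_present[occ$donor == "LIG@C1"], 50L)
  expect_equal(occ$mean_distance[occ$donor == "LIG@C1"], 3, tolerance = 1e-9)
  expect_false(is.unsorted(rev(occ$occupancy)))
  # occupancy is non-decreasing in the distance cutoff
  occ6 <- hbond_occupancy(traj, select_atoms(traj$topology, "ligand", resname = "LIG"),
                          dist_cutoff = 6)
  expect_true(all(occ6$occupancy[match(occ$donor, occ6$donor)] >= occ$occupancy))
})

test_that("the strict angle criterion distinguishes donor geometries", {
  # donor O2 at (1,0,0) with H pointing at the water: angle ~180, passes;
  # moving the water behind the donor fails the angle but not the distance
  nf <- 2
  pos <- array(NA_real_, c(1, 3, nf))
  pos[1, , 1] <- c(3.8, 0, 0)     # in front, along O-H
  pos[1, , 2] <- c(-1.6, 0, 0)    # behind the donor, 2.6 A away
  lig <- rbind(c(0, 0, 0), c(1, 0, 0))
  traj <- script_traj(pos, lig_xyz = lig)
  # append a hydrogen on the donor by rebuilding the topology
  at <- traj$topology$atoms
  h <- at[1, ]
  h$serial <- nrow(at) + 1L
  h$name <- "HO2"
  h$element <- "H"
  h$x <- 2.0
  h$y <- 0
  h$z <- 0
  topo <- hydrosite:::new_structure(rbind(at, h))
  coords <- array(NA_real_, c(nrow(at) + 1L, 3, nf))
  coords[seq_len(nrow(at)), , ] <- traj$coords
  coords[nrow(at) + 1L, , ] <- matrix(c(2, 0, 0), 3, nf)
  traj2 <- hydrosite:::new_trajectory(topo, coords)
  lig_sel <- select_atoms(traj2$topology, "ligand", resname = "LIG")
  strict <- hbond_occupancy(traj2, lig_sel, dist_cutoff = 4,
                            angle_cutoff = 120, use_angle = TRUE)
  o2 <- strict[strict$donor == "LIG@O2", ]
  expect_equal(o2$occupancy, 50)   # only the in-front frame passes
  expect_error(hbond_occupancy(traj, select_atoms(traj$topology, "ligand", resname = "LIG"),
                               use_angle = TRUE), "hydrogen")
})

test_that("residence statistics match hand counts on 111001111100", {
  bits <- as.integer(strsplit("111001111100", "")[[1]])
  nf <- length(bits)
  pos <- array(NA_real_, c(1, 3, nf))
  site <- c(0, 3, 0)
  for (f in seq_len(nf)) {
    pos[1, , f] <- if (bits[f] == 1) site else c(0, 30, 0)
  }
  traj <- script_traj(pos, frame_interval = 2)
  r0 <- residence_time(traj, 501, site, site_radius = 1.4, gap_tolerance = 0)
  expect_equal(r0$longest_run_frames, 5L)      # frames 6-10
  expect_equal(r0$longest_run_ps, 10)
  expect_equal(r0$n_visits, 2L)                # 111 and 11111
  expect_equal(r0$total_occupancy, 100 * 8 / 12, tolerance = 1e-9)
  r2 <- residence_time(traj, 501, site, site_radius = 1.4, gap_tolerance = 2)
  expect_equal(r2$n_visits, 1L)                # the 2-frame gap is bridged
  expect_equal(r2$longest_run_frames, 10L)     # frames 1-10 incl. the gap
  expect_error(residence_time(traj, 999, site), "unknown water")
})

test_that("run scanning equals the brute-force window scan on random bitstrings", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    bits <- stats::rbinom(n, 1, 0.5)
    gap <- sample(0:3, 1)
    runs <- hydrosite:::presence_runs(bits, gap)
    want <- brute_longest_window(bits, gap)
    got <- if (nrow(runs)) max(runs$length) else 0L
    expect_equal(got, want)
    expect_equal(sum(runs$n_present), sum(bits))
  }
})

test_that("an empty-water trajectory gives all-zero hydration output", {
  pos <- array(NA_real_, c(0, 3, 5))
  traj <- script_traj(pos)
  lig <- select_atoms(traj$topology, "ligand", resname = "LIG")
  sh <- shell_counts(traj, lig)
  expect_equal(sh$first, rep(0L, 5))
  expect_equal(sh$second, rep(0L, 5))
  expect_equal(nrow(hbond_occupancy(traj, lig)), 0L)
})
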