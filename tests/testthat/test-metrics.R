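random_ca_snapshot <- function(n, seed) {
  set.seed(seed)
  at <- interlock:::new_atoms_tibble(chain = "A", resno = seq_len(n),
                                     insert = "", resname = "ALA",
                                     atom_name = "CA", element = "C")
  snapshot(at, matrix(rnorm(3 * n, sd = 5), ncol = 3))
}

test_that("superposition RMSD matches an independent SVD-based oracle", {
  set.seed(21)
  for (rep in 1:5) {
    ref <- random_ca_snapshot(30, seed = rep)
    R <- random_rotation()
    noisy <- ref$xyz %*% R + matrix(rnorm(90, sd = 0.5), ncol = 3) +
      matrix(c(4, -2, 7), 30, 3, byrow = TRUE)
    mob <- snapshot(ref$atoms, noisy)
    fit <- kabsch_superpose(mob, ref, selection = "all")
    expect_lt(abs(fit$rmsd - kabsch_oracle_rmsd(noisy, ref$xyz)), 1e-8)
  }
})

test_that("superposition removes pure rotations and translations entirely", {
  ref <- random_ca_snapshot(25, seed = 2)
  moved <- snapshot(ref$atoms,
                    ref$xyz %*% random_rotation() +
                      matrix(c(10, 20, -5), 25, 3, byrow = TRUE))
  expect_lt(kabsch_superpose(moved, ref, selection = "all")$rmsd, 1e-9)
})

test_that("atom selections pick the expected subsets", {
  snap <- generate_toy_complex(demo_spec())
  at <- snap$atoms
  expect_equal(sum(interlock:::selection_mask(at, "calpha")), 24)
  expect_equal(sum(interlock:::selection_mask(at, "heavy")), nrow(at))
  expect_true(all(interlock:::selection_mask(at, "all")))
  expect_error(kabsch_superpose(snap, snap, selection = rep(FALSE, nrow(at))),
               class = "interlock_spec_error")
})

test_that("the radius of gyration matches its closed form", {
  snap <- random_ca_snapshot(40, seed = 5)
  m <- snap$atoms$mass
  com <- colSums(snap$xyz * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(snap$xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(snap), oracle)
  # equal-mass atoms: weighting cannot matter
  expect_equal(radius_of_gyration(snap, mass_weighted = FALSE), oracle)
})

test_that("RMSD and Rg series carry frame times from the spacing metadata", {
  base <- generate_toy_complex(demo_spec())
  ens <- generate_ensemble(base, n_frames = 4, noise_sd = 0.1, seed = 3,
                           frame_spacing = 500)
  rs <- rmsd_series(ens)
  expect_equal(rs$time, c(0, 500, 1000, 1500))
  expect_lt(rs$rmsd[1], 1e-9)       # first frame is the default reference
  expect_true(all(rs$rmsd[-1] > 0))
  rg <- rg_series(ens)
  expect_equal(nrow(rg), 4)
  expect_true(all(rg$rg > 0))
})

test_that("interface separation shows up as a large backbone RMSD", {
  base <- generate_toy_complex(demo_spec())
  ens <- generate_ensemble(base, n_frames = 5, noise_sd = 0,
                           broken_fraction = 0.4)
  rs <- rmsd_series(ens)
  expect_lt(max(rs$rmsd[1:3]), 1e-9)
  expect_gt(min(rs$rmsd[4:5]), 5)
})

test_that("per-residue fluctuation singles out the residue that actually moves", {
  snap <- random_ca_snapshot(30, seed = 9)
  up <- snap$xyz; up[7, 3] <- up[7, 3] + 2
  down <- snap$xyz; down[7, 3] <- down[7, 3] - 2
  ens <- ensemble(snap$atoms, list(up, down, up, down))
  rf <- rmsf(ens, window = 1)
  expect_equal(nrow(rf), 30)
  expect_equal(which.max(rf$rmsf), 7)
  # the moving residue oscillates +-2 about the mean; superposition of the 29
  # static residues can only absorb a small part of that
  expect_gt(rf$rmsf[7], 1.8)
  expect_lt(max(rf$rmsf[-7]), 0.5)
})

test_that("fluctuation windows select trailing frames or explicit indices", {
  snap <- random_ca_snapshot(10, seed = 4)
  shifted <- snap$xyz + matrix(rnorm(30, sd = 0.3), ncol = 3)
  frames <- list(snap$xyz, shifted, snap$xyz, snap$xyz)
  ens <- ensemble(snap$atoms, frames)
  # trailing half excludes the perturbed frame 2 entirely
  rf_tail <- rmsf(ens, window = 0.5)
  expect_lt(max(rf_tail$rmsf), 1e-9)
  rf_full <- rmsf(ens, window = c(1, 2))
  expect_gt(max(rf_full$rmsf), 0)
  expect_error(rmsf(ens, window = c(2)), class = "interlock_spec_error")
})
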