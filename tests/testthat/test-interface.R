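# two-residue snapshot with a LYS NZ donor (plus optional hydrogen) on chain A
# and an ASP OD1 acceptor on chain B, at configurable positions
donor_acceptor_snapshot <- function(h_pos = NULL, d_pos = c(0, 0, 0),
                                    a_pos = c(3, 0, 0)) {
  names <- c("NZ", "OD1")
  elements <- c("N", "O")
  resnames <- c("LYS", "ASP")
  chains <- c("A", "B")
  resnos <- c(1, 1)
  xyz <- rbind(d_pos, a_pos)
  if (!is.null(h_pos)) {
    names <- c("NZ", "HZ1", "OD1")
    elements <- c("N", "H", "O")
    resnames <- c("LYS", "LYS", "ASP")
    chains <- c("A", "A", "B")
    resnos <- c(1, 1, 1)
    xyz <- rbind(d_pos, h_pos, a_pos)
  }
  at <- interlock:::new_atoms_tibble(chain = chains, resno = resnos,
                                     insert = "", resname = resnames,
                                     atom_name = names, element = elements)
  snapshot(at, xyz)
}

test_that("interface residues are exactly the planted contact pairs", {
  snap <- generate_toy_complex(demo_spec())
  ir <- interface_residues(snap)
  expect_setequal(ir$node_id, c("A:3", "A:6", "B:4", "B:7"))
  expect_equal(ir$min_cross_distance[ir$node_id == "A:3"], 3.0)
  # symmetric in the chain arguments
  ir_rev <- interface_residues(snap, "B", "A")
  expect_setequal(ir_rev$node_id, ir$node_id)
  expect_error(interface_residues(snap, "A", "Z"),
               class = "interlock_lookup_error")
})

test_that("hydrogen bonds require donor-acceptor proximity", {
  hb <- detect_hbonds(donor_acceptor_snapshot(a_pos = c(3.4, 0, 0)))
  expect_equal(nrow(hb), 1)
  expect_identical(hb$donor_residue, "A:1")
  expect_identical(hb$acceptor_residue, "B:1")
  expect_equal(hb$distance, 3.4)
  none <- detect_hbonds(donor_acceptor_snapshot(a_pos = c(3.6, 0, 0)))
  expect_equal(nrow(none), 0)
})

test_that("the angle criterion only engages when hydrogens are present", {
  # hydrogen pointing at the acceptor: H-D-A angle 0, bond kept
  aligned <- donor_acceptor_snapshot(h_pos = c(1.0, 0, 0))
  expect_equal(nrow(detect_hbonds(aligned)), 1)
  # hydrogen perpendicular to the donor-acceptor axis: angle 90, rejected
  skew <- donor_acceptor_snapshot(h_pos = c(0, 1.0, 0))
  expect_equal(nrow(detect_hbonds(skew)), 0)
  # without hydrogens the same heavy-atom geometry passes
  bare <- donor_acceptor_snapshot()
  expect_equal(nrow(detect_hbonds(bare)), 1)
})

test_that("the planted bond in the toy complex is the only cross-chain hydrogen bond", {
  snap <- generate_toy_complex(demo_spec())
  hb <- detect_hbonds(snap)
  expect_equal(nrow(hb), 1)
  expect_identical(hb$donor_atom, "NZ")
  expect_identical(hb$acceptor_atom, "OD1")
  expect_equal(hb$distance, 3.0)
})

test_that("minimum-distance series jump when the interface separates", {
  base <- generate_toy_complex(demo_spec())
  ens <- generate_ensemble(base, n_frames = 10, noise_sd = 0,
                           broken_fraction = 0.3)
  md <- min_distance_series(ens, c("A:3", "B:4"))
  expect_equal(md$distance[1:7], rep(3.0, 7))
  expect_equal(md$distance[8:10], rep(23.0, 3))
  expect_equal(md$time, (0:9) * 1000)
})

test_that("interface pseudoenergies decompose exactly on the planted toy interface", {
  snap <- generate_toy_complex(demo_spec())
  eb <- interface_energies(snap)
  # one hydrogen bond, one opposite-charge pair at 3.0 A, and 9 heavy-atom
  # van der Waals contacts per contact slot (2 slots)
  expect_equal(eb$hbond_energy, -1.5)
  expect_equal(eb$electrostatic_energy, -1.0)
  expect_equal(eb$vdw_energy, 18 * -0.2)
  expect_equal(eb$total_stabilizing, -6.1)
  expect_equal(eb$n_interface_residues, 4)
  expect_equal(eb$normalized_per_residue, -6.1 / 4)
})

test_that("like charges across the interface are scored as repulsive", {
  at <- interlock:::new_atoms_tibble(
    chain = c("A", "B"), resno = c(1, 1), insert = "",
    resname = c("LYS", "LYS"), atom_name = c("NZ", "NZ"), element = "N"
  )
  snap <- snapshot(at, rbind(c(0, 0, 0), c(5, 0, 0)))
  eb <- interface_energies(snap)
  expect_equal(eb$electrostatic_energy, +1.0)
})

test_that("hotspot attribution conserves energy and applies the threshold", {
  snap <- generate_toy_complex(demo_spec())
  eb <- interface_energies(snap)
  hs <- hotspots(snap)
  expect_equal(sum(hs$energy), eb$total_stabilizing)
  # hydrogen-bonding residues: -1.5/2 (hbond) - 1.0/2 (elec) - 9*0.2/2 (vdw)
  expect_equal(hs$energy[hs$node_id == "A:3"], -2.15)
  expect_true(hs$hotspot[hs$node_id == "A:3"])
  # plain contact residues: only the vdW share
  expect_equal(hs$energy[hs$node_id == "A:6"], -0.9)
  expect_false(hs$hotspot[hs$node_id == "A:6"])
})

test_that("a separated interface yields no residues and an undefined normalization", {
  base <- generate_toy_complex(demo_spec())
  ens <- generate_ensemble(base, n_frames = 2, noise_sd = 0,
                           broken_fraction = 1)
  snap <- get_snapshot(ens, 1)
  expect_equal(nrow(interface_residues(snap)), 0)
  eb <- interface_energies(snap)
  expect_equal(eb$total_stabilizing, 0)
  expect_true(is.na(eb$normalized_per_residue))
  expect_equal(nrow(hotspots(snap)), 0)
})

test_that("energy series respect the frame stride", {
  base <- generate_toy_complex(demo_spec())
  ens <- generate_ensemble(base, n_frames = 6, noise_sd = 0)
  ets <- energy_time_series(ens, stride = 2)
  expect_equal(ets$frame, c(1, 3, 5))
  expect_equal(ets$total_stabilizing, rep(-6.1, 3))
  expect_error(energy_time_series(ens, stride = 0),
               class = "interlock_spec_error")
})
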