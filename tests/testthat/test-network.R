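test_that("interaction strength equals the contact count under unit normalization", {
  snap <- make_contact_snapshot(4, data.frame(i = c(1, 2), j = c(2, 4),
                                              n_contacts = c(3L, 7L)))
  p <- unit_params()
  expect_equal(interaction_strength(snap, "A:10", "A:20", p), 3)
  expect_equal(interaction_strength(snap, "A:20", "A:40", p), 7)
  expect_equal(interaction_strength(snap, "A:10", "A:40", p), 0)
})

test_that("network edges honour the strength cutoff and contact counts", {
  snap <- make_contact_snapshot(5, data.frame(i = c(1, 1, 2), j = c(2, 3, 5),
                                              n_contacts = c(1L, 4L, 6L)))
  net <- build_network(snap, unit_params(i_min = 2))
  expect_equal(nrow(net$edges), 2)   # the 1-contact edge falls below i_min = 2
  expect_setequal(paste(net$edges$node_i, net$edges$node_j),
                  c("A:10 A:30", "A:20 A:50"))
  expect_equal(sort(net$edges$n_contacts), c(4L, 6L))
  expect_equal(sort(net$edges$strength), c(4, 6))
})

test_that("covalent neighbours are excluded within a chain but not across chains", {
  at <- interlock:::new_atoms_tibble(
    chain = c("A", "A", "A", "B"), resno = c(1, 2, 4, 1), insert = "",
    resname = "ALA", atom_name = c("CB", "CB", "CB", "CB"), element = "C"
  )
  # A:1-A:2 (sep 1, excluded), A:2-A:4 (sep 2, excluded), A:4-B:1 (kept)
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0))
  net <- build_network(snapshot(at, xyz), unit_params(i_min = 0.1))
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$node_i, "A:4")
  expect_identical(net$edges$node_j, "B:1")
})

test_that("an unknown residue type fails loudly instead of getting silent strength", {
  at <- interlock:::new_atoms_tibble(
    chain = c("A", "B"), resno = c(1, 1), insert = "",
    resname = "XYZ", atom_name = "CB", element = "C"
  )
  snap <- snapshot(at, rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(build_network(snap, unit_params()),
               class = "interlock_config_error")
})

test_that("the largest-cluster profile is non-increasing along the strength grid", {
  snap <- generate_toy_complex(demo_spec())
  prof <- largest_cluster_profile(snap)
  expect_true(all(diff(prof$largest_cluster) <= 0))
  expect_equal(prof$i_min, seq(0, 10, by = 0.5))
  expect_error(largest_cluster_profile(snap, i_min_grid = c(2, 1)),
               class = "interlock_spec_error")
  expect_error(largest_cluster_profile(snap, i_min_grid = numeric()),
               class = "interlock_spec_error")
})

test_that("a flat cluster profile reports that no transition exists", {
  prof <- tibble::tibble(i_min = c(0, 1, 2), largest_cluster = c(4, 4, 4))
  sel <- select_imin(prof)
  expect_false(sel$transition_found)
  expect_true(is.na(sel$i_min))
})

test_that("edge frequency across frames drives dynamic stability", {
  snap <- make_contact_snapshot(3, data.frame(i = c(1, 2), j = c(2, 3),
                                              n_contacts = c(3L, 3L)))
  # edge 2-3 is deleted in 3 of 4 frames by detaching residue 3's pseudo-atoms
  broken <- detach_residue(snap, "A:30")
  ens <- ensemble(snap$atoms, list(snap$xyz, broken, broken, broken))
  en <- stable_network(ens, unit_params(), stability = 0.5)
  freq <- tidy(en)
  e12 <- freq[freq$node_i == "A:10" & freq$node_j == "A:20", ]
  e23 <- freq[freq$node_i == "A:20" & freq$node_j == "A:30", ]
  expect_equal(e12$frequency, 1)
  expect_true(e12$stable)
  expect_equal(e23$frequency, 0.25)
  expect_false(e23$stable)
  expect_equal(nrow(en$stable_network$edges), 1)
})

test_that("an edge present in exactly half the frames counts as stable (inclusive cutoff)", {
  snap <- make_contact_snapshot(2, data.frame(i = 1, j = 2, n_contacts = 3L))
  broken <- detach_residue(snap, "A:20")
  ens <- ensemble(snap$atoms, list(snap$xyz, broken))
  en <- stable_network(ens, unit_params(), stability = 0.5)
  expect_equal(en$edge_frequency$frequency, 0.5)
  expect_true(en$edge_frequency$stable)
})

test_that("network parameter validation rejects impossible cutoffs", {
  expect_error(network_params(contact_cutoff = -1),
               class = "interlock_spec_error")
  expect_error(network_params(i_min = -0.5), class = "interlock_spec_error")
})
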