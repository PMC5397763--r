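test_that("hop-count shortest paths prefer fewer edges and are reconstructed in order", {
  net <- abstract_network(5, data.frame(i = c(1, 2, 3, 4, 1),
                                        j = c(2, 3, 4, 5, 5)))
  p <- shortest_path(net, "A:1", "A:4")
  expect_identical(p, c("A:1", "A:5", "A:4"))
  expect_identical(shortest_path(net, "A:1", "A:1"), "A:1")
})

test_that("equally short routes break ties toward the canonically smallest residue", {
  net <- abstract_network(4, data.frame(i = c(1, 2, 1, 3), j = c(2, 4, 3, 4)))
  expect_identical(shortest_path(net, "A:1", "A:4"), c("A:1", "A:2", "A:4"))
})

test_that("strength-weighted costs can favour a longer but stronger route", {
  net <- abstract_network(4, data.frame(i = c(1, 1, 2), j = c(4, 2, 4),
                                        strength = c(1, 10, 10)))
  expect_identical(shortest_path(net, "A:1", "A:4"), c("A:1", "A:4"))
  expect_identical(shortest_path(net, "A:1", "A:4", weighted = TRUE),
                   c("A:1", "A:2", "A:4"))
})

test_that("disconnected residues yield no path and unknown residues an error", {
  net <- abstract_network(4, data.frame(i = 1, j = 2))
  expect_null(shortest_path(net, "A:1", "A:3"))
  expect_error(shortest_path(net, "A:1", "A:99"),
               class = "interlock_lookup_error")
})

test_that("all-pairs distances match an independent breadth-first search", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(4:20, 1)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    m <- sample.int(nrow(pairs), 1)
    sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    net <- abstract_network(n, data.frame(i = sel[, 1], j = sel[, 2]))
    d <- interlock:::floyd_warshall(interlock:::network_cost_matrix(net))
    g <- igraph::graph_from_data_frame(
      net$edges[, c("node_i", "node_j")], directed = FALSE,
      vertices = net$nodes$node_id
    )
    ref <- igraph::distances(g)[net$nodes$node_id, net$nodes$node_id]
    expect_equal(unname(d), unname(ref))
  }
})

test_that("per-frame path variation is summarised by consensus and stable-network routes", {
  snap <- make_contact_snapshot(4, data.frame(i = c(1, 2, 1, 4),
                                              j = c(2, 3, 4, 3),
                                              n_contacts = c(3L, 3L, 3L, 3L)))
  upper <- detach_residue(snap, "A:40")  # route 10-20-30 only
  lower <- detach_residue(snap, "A:20")  # route 10-40-30 only
  ens <- ensemble(snap$atoms, list(upper, upper, lower))
  pr <- ensemble_paths(ens, "A:10", "A:30", unit_params(),
                       stability = 0.5, consensus = 0.5)
  expect_equal(pr$average_length, 2)
  expect_identical(pr$per_frame$path[1], "A:10 -> A:20 -> A:30")
  expect_identical(pr$per_frame$path[3], "A:10 -> A:40 -> A:30")
  # A:40 appears in 1/3 of the per-frame paths, below the 50% consensus
  expect_setequal(pr$consensus_nodes, c("A:10", "A:20", "A:30"))
  expect_identical(pr$stable_path, c("A:10", "A:20", "A:30"))
  g <- glance(pr)
  expect_equal(g$n_with_path, 3)
  expect_equal(g$stable_path_length, 2)
})

test_that("frames without a route are excluded from the average path length", {
  snap <- make_contact_snapshot(3, data.frame(i = c(1, 2), j = c(2, 3),
                                              n_contacts = c(3L, 3L)))
  broken <- detach_residue(snap, "A:20")
  ens <- ensemble(snap$atoms, list(snap$xyz, broken))
  pr <- ensemble_paths(ens, "A:10", "A:30", unit_params())
  expect_identical(pr$per_frame$found, c(TRUE, FALSE))
  expect_equal(pr$average_length, 2)
})

test_that("shared intermediates across routes exclude every endpoint", {
  mk <- function(cons, src, snk) {
    structure(list(consensus_nodes = cons, source = src, sink = snk),
              class = "path_result")
  }
  r1 <- mk(c("A:1", "A:5", "A:7", "A:9"), "A:1", "A:9")
  r2 <- mk(c("A:2", "A:5", "A:7", "A:1"), "A:2", "A:7")
  expect_identical(common_path_residues(list(r1, r2)), "A:5")
  expect_error(common_path_residues(list(r1)), class = "interlock_spec_error")
})
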