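test_that("complex specifications are validated before any geometry is built", {
  expect_error(toy_complex_spec(5, 5, contact_pairs = list(c(6, 1))),
               class = "interlock_spec_error")
  expect_error(toy_complex_spec(5, 5, contact_pairs = list(c(1, 2)),
                                hbond_pairs = list(c(1, 3))),
               class = "interlock_spec_error")
  expect_error(
    toy_complex_spec(8, 8, contact_pairs = list(c(1, 2), c(1, 5)),
                     hbond_pairs = list(c(1, 2), c(1, 5))),
    class = "interlock_spec_error"
  )
  expect_error(toy_complex_spec(5, 5, path_chain = c(2)),
               class = "interlock_spec_error")
  expect_error(toy_complex_spec(5, 5, path_chain = c(2, 2, 4)),
               class = "interlock_spec_error")
  expect_error(toy_complex_spec(5, 5, path_chain = c(2, 9)),
               class = "interlock_spec_error")
})

test_that("planted contacts are within range and everything else is kept apart", {
  spec <- demo_spec()
  snap <- generate_toy_complex(spec)
  at <- snap$atoms
  # min cross-chain heavy-atom distance per residue pair
  cross_min <- function(ra, rb) {
    ia <- which(at$chain == "A" & at$resno == ra)
    ib <- which(at$chain == "B" & at$resno == rb)
    A <- snap$xyz[ia, , drop = FALSE]; B <- snap$xyz[ib, , drop = FALSE]
    sqrt(max(min(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)), 0))
  }
  planted <- vapply(spec$contact_pairs, paste, character(1), collapse = "-")
  for (ra in 1:12) for (rb in 1:12) {
    d <- cross_min(ra, rb)
    if (paste(ra, rb, sep = "-") %in% planted) {
      expect_lte(d, 4.5)
    } else {
      expect_gte(d, 8)
    }
  }
})

test_that("planted hydrogen-bond pairs carry exact donor-acceptor geometry", {
  snap <- generate_toy_complex(demo_spec())
  at <- snap$atoms
  nz <- which(at$atom_name == "NZ")
  od <- which(at$atom_name == "OD1")
  expect_equal(length(nz), 1)
  expect_identical(at$node_id[nz], "A:3")
  expect_identical(at$resname[nz], "LYS")
  expect_identical(at$node_id[od], "B:4")
  expect_identical(at$resname[od], "ASP")
  expect_equal(sqrt(sum((snap$xyz[nz, ] - snap$xyz[od, ])^2)), 3.0)
})

test_that("broken frames form a contiguous final block with the interface separated", {
  base <- generate_toy_complex(demo_spec())
  ens <- generate_ensemble(base, n_frames = 10, noise_sd = 0,
                           broken_fraction = 0.3, seed = 2)
  expect_identical(attr(ens, "broken_frames"), 8:10)
  intact <- get_snapshot(ens, 1)
  broken <- get_snapshot(ens, 9)
  expect_gt(nrow(interface_residues(intact)), 0)
  expect_equal(nrow(interface_residues(broken)), 0)
  # rigid translation: chain B internal geometry is unchanged
  b <- ens$atoms$chain == "B"
  expect_equal(as.vector(dist(broken$xyz[b, ])),
               as.vector(dist(intact$xyz[b, ])))
})

test_that("scattered broken frames are reproducible and have the right count", {
  base <- generate_toy_complex(demo_spec())
  e1 <- generate_ensemble(base, n_frames = 10, broken_fraction = 0.4,
                          scatter_broken = TRUE, seed = 9)
  e2 <- generate_ensemble(base, n_frames = 10, broken_fraction = 0.4,
                          scatter_broken = TRUE, seed = 9)
  expect_identical(attr(e1, "broken_frames"), attr(e2, "broken_frames"))
  expect_equal(length(attr(e1, "broken_frames")), 4)
})

test_that("ensemble generation validates its arguments", {
  base <- generate_toy_complex(demo_spec())
  expect_error(generate_ensemble(base, n_frames = 0),
               class = "interlock_spec_error")
  expect_error(generate_ensemble(base, n_frames = 2, noise_sd = -1),
               class = "interlock_spec_error")
  expect_error(generate_ensemble(base, n_frames = 2, broken_fraction = 1.5),
               class = "interlock_spec_error")
})

test_that("the planted truth file lists contacts, hydrogen bonds and the path", {
  spec <- demo_spec()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_truth(spec, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4)  # header + 2 contacts + 1 path
  expect_match(lines[2], "^hbond_contact\tA\t3\tB\t4$")
  expect_match(lines[4], "^path\tA\t2,5,8,11")
})
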