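test_that("gap filtering treats X as a gap and reports the retained column map", {
  x <- msa(sprintf("s%d", 1:10), c(
    # col1 clean, col2 30% '-', col3 40% 'X', col4 60% '-'
    "AAAA", "C-X-", "D-X-", "E-X-", "CAX-", "CAA-", "DAA-", "EAAA", "AAAA", "CAAA"
  ))
  fil <- remove_gappy_columns(x, max_gap_fraction = 0.30)
  expect_identical(fil$column_map, c(1L, 2L))
  expect_equal(fil$msa$n_cols, 2)
  expect_error(remove_gappy_columns(msa("a", "--"), 0.3),
               class = "interlock_alignment_length_error")
})

test_that("domain concatenation demands identically ordered identifiers", {
  a <- msa(c("x", "y"), c("AC", "DE"))
  b <- msa(c("y", "x"), c("FG", "HI"))
  expect_error(concatenate_alignments(a, b),
               class = "interlock_pairing_error")
  cc <- concatenate_alignments(a, msa(c("x", "y"), c("FG", "HI")))
  expect_equal(cc$msa$seqs, c("ACFG", "DEHI"))
  expect_equal(cc$partition$boundary, 2)
})

test_that("identity-cluster weights downweight duplicated rows to unit total", {
  x <- msa(sprintf("s%d", 1:5),
           c("ACDEF", "ACDEF", "ACDEF", "WYWYW", "KLKLK"))
  w <- msa_weights(x, identity_threshold = 0.8)
  expect_equal(w, c(1/3, 1/3, 1/3, 1, 1))
  expect_equal(effective_sequences(x, 1, 2, weights = w), 3)
})

test_that("the effective sequence count ignores rows gapped at either column", {
  x <- msa(sprintf("s%d", 1:4), c("A-", "AC", "-C", "AC"))
  expect_equal(effective_sequences(x, 1, 2), 2)
  expect_equal(effective_sequences(x, 1, 1), 3)
})

test_that("the pseudocount weight is one at zero depth and decays monotonically", {
  p <- pseudocount_params()
  expect_equal(pseudocount_weight(0, p), 1)
  expect_equal(pseudocount_weight(0, pseudocount_params(0.3, 2)), 1)
  ne <- seq(0, 200, by = 5)
  tau <- pseudocount_weight(ne, p)
  expect_true(all(diff(tau) < 0))
  expect_lt(pseudocount_weight(100, p), 0.1)
  expect_error(pseudocount_params(a = 0), class = "interlock_spec_error")
})

test_that("joint distributions are proper probabilities with matching marginals", {
  gen <- generate_coupled_msa(n_seqs = 40, length_a = 6, length_b = 6,
                              gap_fraction = 0.1, seed = 8)
  cc <- concatenate_alignments(gen$msa_a, gen$msa_b)
  jd <- joint_probability(cc$msa, 2, 9)
  expect_equal(sum(jd$pseudocounted), 1)
  expect_equal(sum(jd$counts_based), 1)
  expect_equal(jd$marginal_i, rowSums(jd$pseudocounted))
  expect_equal(jd$marginal_j, colSums(jd$pseudocounted))
  expect_true(jd$tau > 0 && jd$tau < 1)
  expect_equal(jd$tau, pseudocount_weight(jd$neff))
})

test_that("column pairs with almost no shared coverage are refused", {
  x <- msa(sprintf("s%d", 1:4), c("A-", "-C", "-C", "-C"))
  expect_error(joint_probability(x, 1, 2),
               class = "interlock_insufficient_data_error")
})

test_that("mutual information vanishes for a product distribution", {
  p <- runif(20); p <- p / sum(p)
  q <- runif(20); q <- q / sum(q)
  expect_lt(abs(mutual_information(p %o% q)), 1e-12)
})

test_that("ranking is by corrected score with deterministic tie-breaking", {
  gen <- generate_coupled_msa(n_seqs = 60, length_a = 12, length_b = 12,
                              couplings = list(coupling_spec(3, 20, 0.9)),
                              seed = 2)
  res <- predict_coevolving_pairs(gen$msa_a, gen$msa_b, top_n = Inf)
  tab <- tidy(res)
  expect_true(all(diff(tab$MIp) <= 1e-12))
  expect_identical(tab$rank, seq_len(nrow(tab)))
  # intra-domain pairs closer than min_separation are absent
  intra <- tab[tab$class != "inter", ]
  expect_true(all(abs(intra$j - intra$i) >= 5))
  # inter pairs straddle the original boundary of 12 columns
  inter <- tab[tab$class == "inter", ]
  expect_true(all(inter$i <= 12 & inter$j > 12))
  g <- glance(res)
  expect_equal(g$n_inter + g$n_intra_a + g$n_intra_b, g$n_pairs_reported)
})

test_that("reported positions survive gap filtering in original coordinates", {
  # build alignments where known columns are removed by the gap filter
  gen <- generate_coupled_msa(n_seqs = 50, length_a = 8, length_b = 8,
                              couplings = list(coupling_spec(5, 11, 1)),
                              gap_fraction = 0, seed = 13)
  # force column 2 of A and column 1 of B to be all-gap
  blank <- function(m, col) {
    s <- strsplit(m$seqs, "")
    msa(m$ids, vapply(s, function(x) {
      x[col] <- "-"; paste(x, collapse = "")
    }, character(1)))
  }
  a <- blank(gen$msa_a, 2)
  b <- blank(gen$msa_b, 1)
  res <- predict_coevolving_pairs(a, b, top_n = 3, min_separation = 2)
  top <- tidy(res)[1, ]
  # planted pair must still be reported at its original positions (5, 8+3)
  expect_equal(top$i, 5)
  expect_equal(top$j, 11)
  expect_false(any(tidy(res, all = TRUE)$i == 2))
  expect_false(any(tidy(res, all = TRUE)$j == 9))
})
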