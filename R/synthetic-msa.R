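# Synthetic alignments with planted covariation.
#
# Columns are i.i.d. draws from per-column profiles (profiles drawn once per
# column from a symmetric Dirichlet) except for planted column pairs, where
# with probability `strength` the letter at column j is a fixed bijection of
# the letter at column i. This gives the co-evolution stage a controllable
# ground truth: strength 1 with no gaps makes the pair's empirical joint a
# permutation matrix, strength 0 makes the pair independent.

#' Specify a planted coupling between two alignment columns
#'
#' @param i,j 1-based column indices in the *concatenated* alignment
#'   (columns `1..length_a` belong to domain A, the rest to domain B).
#' @param strength Probability in `[0, 1]` that a row obeys the coupling
#'   bijection; rows that do not obey draw independently from column j's
#'   profile.
#' @param bijection Optional permutation of [aa_alphabet()] (character vector
#'   of length 20, named or positional). Default `NULL` draws a random
#'   permutation from the generator seed.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(i, j, strength = 0.9, bijection = NULL) {
  if (i == j) stop_interlock("coupling columns must differ", "interlock_spec_error")
  if (strength < 0 || strength > 1) {
    stop_interlock("coupling strength must be in [0, 1]", "interlock_spec_error")
  }
  if (!is.null(bijection)) {
    if (!setequal(bijection, aa_alphabet()) || length(bijection) != 20) {
      stop_interlock("bijection must be a permutation of the 20-letter alphabet",
                     "interlock_spec_error")
    }
    if (is.null(names(bijection))) names(bijection) <- aa_alphabet()
  }
  structure(list(i = as.integer(i), j = as.integer(j),
                 strength = strength, bijection = bijection),
            class = "coupling_spec")
}

#' Generate a pair of domain alignments with planted covariation
#'
#' Emulates a two-domain study alignment: both per-domain MSAs share the same
#' ordered sequence identifiers, so they can be concatenated column-wise.
#' Defaults mirror the study conditions of the original analysis: 97
#' sequences, 153 columns for the N-terminal domain and 196 for the TIR
#' domain.
#'
#' @param n_seqs Number of sequences (>= 2).
#' @param length_a,length_b Columns in domain A and domain B.
#' @param couplings List of [coupling_spec()] objects (columns given in
#'   concatenated coordinates).
#' @param gap_fraction Per-cell i.i.d. gap probability in `[0, 1]`.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param profiles Optional `20 x (length_a + length_b)` matrix of per-column
#'   amino-acid probabilities (rows in [aa_alphabet()] order). Default draws
#'   each column's profile from a symmetric Dirichlet.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet used to draw
#'   column profiles when `profiles` is not given.
#' @return List with `msa_a`, `msa_b` ([msa()] objects), `truth` (tibble of
#'   planted pairs with concatenated column indices and class), and `profiles`.
#' @export
generate_coupled_msa <- function(n_seqs = 97, length_a = 153, length_b = 196,
                                 couplings = list(), gap_fraction = 0,
                                 seed = 1, profiles = NULL,
                                 dirichlet_conc = 1) {
  if (n_seqs < 2) stop_interlock("n_seqs must be >= 2", "interlock_spec_error")
  if (gap_fraction < 0 || gap_fraction > 1) {
    stop_interlock("gap_fraction must be in [0, 1]", "interlock_spec_error")
  }
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  L <- length_a + length_b
  for (cp in couplings) {
    if (cp$i > L || cp$j > L || cp$i < 1 || cp$j < 1) {
      stop_interlock("coupling columns out of range of the concatenated alignment",
                     "interlock_spec_error")
    }
  }
  ab <- aa_alphabet()
  set.seed(as.integer(seed))
  if (is.null(profiles)) {
    g <- matrix(rgamma(20 * L, shape = dirichlet_conc), nrow = 20)
    profiles <- sweep(g, 2, colSums(g), "/")
  } else {
    profiles <- as.matrix(profiles)
    stopifnot(nrow(profiles) == 20, ncol(profiles) == L)
    profiles <- sweep(profiles, 2, colSums(profiles), "/")
  }
  rownames(profiles) <- ab

  X <- matrix("", nrow = n_seqs, ncol = L)
  for (c in seq_len(L)) {
    X[, c] <- sample(ab, n_seqs, replace = TRUE, prob = profiles[, c])
  }
  for (cp in couplings) {
    bij <- cp$bijection %||% setNames(sample(ab), ab)
    obey <- runif(n_seqs) < cp$strength
    X[obey, cp$j] <- unname(bij[X[obey, cp$i]])
  }
  if (gap_fraction > 0) {
    X[matrix(runif(n_seqs * L) < gap_fraction, n_seqs, L)] <- "-"
  }
  ids <- sprintf("seq%04d", seq_len(n_seqs))
  rows <- apply(X, 1, paste, collapse = "")
  msa_a <- msa(ids, substr(rows, 1, length_a))
  msa_b <- msa(ids, substr(rows, length_a + 1, L))
  truth <- purrr::map_dfr(couplings, function(cp) {
    tibble(
      i = min(cp$i, cp$j), j = max(cp$i, cp$j), strength = cp$strength,
      class = dplyr::case_when(
        min(cp$i, cp$j) <= length_a & max(cp$i, cp$j) > length_a ~ "inter",
        max(cp$i, cp$j) <= length_a ~ "intra_A",
        TRUE ~ "intra_B"
      )
    )
  })
  list(msa_a = msa_a, msa_b = msa_b, truth = truth, profiles = profiles)
}
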