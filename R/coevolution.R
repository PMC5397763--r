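# Mutual-information co-evolution on a concatenated two-domain alignment.
#
# Pipeline: gap-filter each domain alignment (> max_gap_fraction gapped
# columns removed), concatenate row-wise, estimate a pseudocount-corrected
# joint distribution for every column pair, compute mutual information in
# nats, apply the average-product correction (MIp), rank pairs and classify
# them as intra-domain or inter-domain.
#
# Pseudocount model: P_PP(x_i, y_j) = (1 - tau) P_obs(x_i, y_j) +
# tau q(x_i) q(y_j), with tau = (1 + b) / (exp(a * Neff(i, j)) + b), where
# Neff(i, j) is the (optionally weighted) number of sequences ungapped at
# both columns and q are per-column profiles. tau -> 1 when few sequences are
# available (the pair is shrunk towards the product of profiles) and
# tau -> 0 with many sequences.

#' Pseudocount parameters
#'
#' Constants of the pseudocount weight `tau = (1 + b) / (exp(a * Neff) + b)`.
#' `tau` is 1 at `Neff = 0` for any `(a, b)` and decreases monotonically with
#' `Neff`. The defaults (`a = 0.05`, `b = 10`) keep `tau` close to 1 for very
#' small alignments and push it below 0.1 by roughly 90 effective sequences.
#'
#' @param a,b Positive constants.
#' @return A `pseudocount_params` list.
#' @export
pseudocount_params <- function(a = 0.05, b = 10) {
  if (a <= 0 || b <= 0) {
    stop_interlock("pseudocount constants a, b must be positive",
                   "interlock_spec_error")
  }
  structure(list(a = a, b = b), class = "pseudocount_params")
}

#' Domain partition of a concatenated alignment
#'
#' @param boundary Last column of domain A in the concatenated alignment.
#' @param n_cols Total number of concatenated columns (optional, for
#'   validation).
#' @param label_a,label_b Domain names.
#' @return A `domain_partition` list.
#' @export
domain_partition <- function(boundary, n_cols = NULL, label_a = "A",
                             label_b = "B") {
  boundary <- as.integer(boundary)
  if (boundary < 1 || (!is.null(n_cols) && boundary >= n_cols)) {
    stop_interlock("boundary must satisfy 1 <= boundary < n_cols",
                   "interlock_spec_error")
  }
  structure(list(boundary = boundary, label_a = label_a, label_b = label_b),
            class = "domain_partition")
}

#' Remove columns with too many gaps
#'
#' Columns whose gap fraction is strictly greater than `max_gap_fraction` are
#' removed (a column with exactly 30% gaps is retained at the default). `X`
#' counts as a gap.
#'
#' @param x An [msa()].
#' @param max_gap_fraction Maximum tolerated gap fraction (default 0.30).
#' @return List with `msa` (filtered alignment) and `column_map` (original
#'   1-based indices of the retained columns).
#' @export
remove_gappy_columns <- function(x, max_gap_fraction = 0.30) {
  stopifnot(inherits(x, "msa"))
  gf <- colMeans(msa_gaps(x))
  keep <- which(gf <= max_gap_fraction)
  if (!length(keep)) {
    stop_interlock("all columns exceed the gap threshold; empty alignment",
                   "interlock_alignment_length_error")
  }
  m <- as.matrix(x)[, keep, drop = FALSE]
  list(
    msa = msa(x$ids, apply(m, 1, paste, collapse = "")),
    column_map = keep
  )
}

#' Concatenate two domain alignments row-wise
#'
#' Both alignments must carry the same sequence identifiers in the same
#' order; no silent reordering is attempted.
#'
#' @param msa_a,msa_b [msa()] objects.
#' @param label_a,label_b Domain names recorded in the partition.
#' @return List with `msa` (concatenated alignment) and `partition`
#'   ([domain_partition()] with `boundary = msa_a$n_cols`).
#' @export
concatenate_alignments <- function(msa_a, msa_b, label_a = "A", label_b = "B") {
  stopifnot(inherits(msa_a, "msa"), inherits(msa_b, "msa"))
  if (!identical(msa_a$ids, msa_b$ids)) {
    stop_interlock("alignments carry different or differently ordered ids",
                   "interlock_pairing_error")
  }
  cat_msa <- msa(msa_a$ids, paste0(msa_a$seqs, msa_b$seqs))
  list(
    msa = cat_msa,
    partition = domain_partition(msa_a$n_cols, cat_msa$n_cols, label_a, label_b)
  )
}

#' Sequence weights by identity clustering
#'
#' Each row is weighted `1 / (number of rows with pairwise identity >= the
#' threshold to it, itself included)`, so a cluster of near-identical rows
#' contributes a total weight of about 1.
#'
#' @param x An [msa()].
#' @param identity_threshold Fractional identity threshold (default 0.8).
#' @return Numeric weight vector, one per row.
#' @export
msa_weights <- function(x, identity_threshold = 0.8) {
  stopifnot(inherits(x, "msa"))
  X <- t(encode_msa(x))            # L x n; NA at gaps
  n <- ncol(X)
  w <- numeric(n)
  for (r in seq_len(n)) {
    both <- !is.na(X) & !is.na(X[, r])
    eq <- X == X[, r] & both
    pid <- colSums(eq) / pmax(colSums(both), 1)
    pid[colSums(both) == 0] <- 0
    w[r] <- 1 / sum(pid >= identity_threshold)
  }
  w
}

#' Effective number of sequences at a column pair
#'
#' The (optionally weighted) number of rows ungapped at both columns `i` and
#' `j`; this is the `Neff(i, j)` controlling the pseudocount weight.
#'
#' @param x An [msa()].
#' @param i,j Column indices.
#' @param weights Optional per-row weights (see [msa_weights()]); default 1.
#' @return Numeric Neff.
#' @export
effective_sequences <- function(x, i, j, weights = NULL) {
  stopifnot(inherits(x, "msa"))
  g <- msa_gaps(x)
  ok <- !g[, i] & !g[, j]
  w <- weights %||% rep(1, length(x$ids))
  sum(w[ok])
}

#' Pseudocount weight tau
#'
#' `tau = (1 + b) / (exp(a * neff) + b)`: 1 at `neff = 0`, strictly
#' decreasing, and tending to 0 as `neff` grows.
#'
#' @param neff Effective sequence count (>= 0).
#' @param params [pseudocount_params()].
#' @return tau in `(0, 1]`.
#' @export
pseudocount_weight <- function(neff, params = pseudocount_params()) {
  stopifnot(all(neff >= 0))
  (1 + params$b) / (exp(params$a * neff) + params$b)
}

# core per-pair joint estimate from 20-column indicator matrices
pair_joint <- function(Mi, Mj, w, qi, qj, params, tau = NULL) {
  cw <- crossprod(Mi * w, Mj)
  n_w <- sum(cw)
  p_obs <- if (n_w > 0) cw / n_w else cw
  tau <- tau %||% pseudocount_weight(n_w, params)
  p_pp <- (1 - tau) * p_obs + tau * (qi %o% qj)
  list(p_obs = p_obs, p_pp = p_pp, neff = n_w, tau = tau)
}

#' Pseudocount-corrected joint distribution of a column pair
#'
#' Observed pair frequencies `P_obs` are computed from rows ungapped at both
#' columns; per-column profiles `q` from rows ungapped at the respective
#' column; the pseudocounted joint is `P_PP = (1 - tau) P_obs + tau q_i q_j`.
#' Marginals are the row/column sums of `P_PP`.
#'
#' @param x An [msa()].
#' @param i,j Column indices.
#' @param params [pseudocount_params()].
#' @param weights Optional per-row weights.
#' @param tau Optional fixed pseudocount weight overriding the `Neff`-based
#'   value (useful to inspect the `tau = 0` / `tau = 1` limits).
#' @return A `joint_distribution` list with fields `counts_based`,
#'   `pseudocounted`, `marginal_i`, `marginal_j`, `q_i`, `q_j`, `neff`, `tau`.
#' @export
joint_probability <- function(x, i, j, params = pseudocount_params(),
                              weights = NULL, tau = NULL) {
  stopifnot(inherits(x, "msa"))
  X <- encode_msa(x)
  w <- weights %||% rep(1, nrow(X))
  ok <- !is.na(X[, i]) & !is.na(X[, j])
  if (sum(ok) < 2) {
    stop_interlock(sprintf("fewer than 2 usable rows at columns %d, %d", i, j),
                   "interlock_insufficient_data_error")
  }
  ind <- function(col) {
    M <- matrix(0, nrow(X), 20)
    obs <- !is.na(col)
    M[cbind(which(obs), col[obs])] <- 1
    M
  }
  Mi <- ind(X[, i]); Mj <- ind(X[, j])
  qcol <- function(M) {
    s <- colSums(M * w)
    tot <- sum(s)
    if (tot > 0) s / tot else s
  }
  qi <- qcol(Mi); qj <- qcol(Mj)
  pj <- pair_joint(Mi, Mj, w, qi, qj, params, tau = tau)
  ab <- aa_alphabet()
  dimnames(pj$p_obs) <- dimnames(pj$p_pp) <- list(ab, ab)
  structure(
    list(counts_based = pj$p_obs, pseudocounted = pj$p_pp,
         marginal_i = rowSums(pj$p_pp), marginal_j = colSums(pj$p_pp),
         q_i = setNames(qi, ab), q_j = setNames(qj, ab),
         neff = pj$neff, tau = pj$tau),
    class = "joint_distribution"
  )
}

#' Mutual information of a joint distribution (nats)
#'
#' `MI = sum_x sum_y P(x, y) log(P(x, y) / (P(x) P(y)))` over the
#' pseudocounted joint, with marginals taken as its row/column sums; zero
#' cells contribute nothing.
#'
#' @param joint A `joint_distribution` (from [joint_probability()]) or a
#'   plain joint probability matrix.
#' @return MI in nats (>= 0 up to rounding).
#' @export
mutual_information <- function(joint) {
  P <- if (inherits(joint, "joint_distribution")) joint$pseudocounted else as.matrix(joint)
  px <- rowSums(P); py <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / outer(px, py)[nz]))
}

#' Average-product correction of a mutual-information matrix
#'
#' `MIp(i, j) = MI(i, j) - MI(i, .) * MI(., j) / MI(., .)`, where `MI(i, .)`
#' is the mean MI of column i against all other columns and `MI(., .)` the
#' mean over all column pairs. When the overall mean is zero no correction is
#' possible and MI is returned unchanged.
#'
#' @param mi Symmetric matrix of MI values (diagonal ignored).
#' @return Symmetric matrix of MIp values (diagonal `NA`).
#' @export
apc_correction <- function(mi) {
  mi <- as.matrix(mi)
  L <- nrow(mi)
  stopifnot(ncol(mi) == L)
  diag(mi) <- NA
  mean_i <- rowMeans(mi, na.rm = TRUE)
  off <- mi[upper.tri(mi)]
  mbar <- mean(off, na.rm = TRUE)
  if (!is.finite(mbar) || mbar == 0) {
    return(mi)
  }
  mip <- mi - outer(mean_i, mean_i) / mbar
  diag(mip) <- NA
  dimnames(mip) <- dimnames(mi)
  mip
}

# all-pairs MI over a concatenated msa; returns list(mi, neff, n_usable)
mi_all_pairs <- function(x, params = pseudocount_params(), weights = NULL) {
  X <- encode_msa(x)
  n <- nrow(X); L <- ncol(X)
  w <- weights %||% rep(1, n)
  Ms <- vector("list", L)
  qs <- vector("list", L)
  U <- matrix(0, n, L)
  for (c in seq_len(L)) {
    M <- matrix(0, n, 20)
    obs <- !is.na(X[, c])
    M[cbind(which(obs), X[obs, c])] <- 1
    Ms[[c]] <- M
    U[, c] <- as.numeric(obs)
    s <- colSums(M * w)
    qs[[c]] <- if (sum(s) > 0) s / sum(s) else s
  }
  n_usable <- crossprod(U)                      # unweighted both-ungapped counts
  mi <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    Mi_w <- Ms[[i]] * w
    for (j in (i + 1):L) {
      if (n_usable[i, j] < 2) next
      cw <- crossprod(Mi_w, Ms[[j]])
      n_w <- sum(cw)
      tau <- pseudocount_weight(n_w, params)
      P <- (1 - tau) * (cw / n_w) + tau * (qs[[i]] %o% qs[[j]])
      px <- rowSums(P); py <- colSums(P)
      nz <- P > 0
      mi[i, j] <- mi[j, i] <- sum(P[nz] * log(P[nz] / outer(px, py)[nz]))
    }
  }
  list(mi = mi, neff = n_usable)
}

#' Predict co-evolving column pairs between two domain alignments
#'
#' Full pipeline: gap-filter each alignment, concatenate, compute MI for all
#' retained column pairs, apply the average-product correction, rank pairs by
#' MIp (descending; ties broken by MI descending, then by column indices),
#' and classify each pair as `intra_A`, `intra_B` or `inter` relative to the
#' domain boundary. Intra-domain pairs closer than `min_separation` columns
#' (in original column coordinates) are excluded to suppress trivial
#' chain-neighbour signal. Reported positions are in original (pre-filter)
#' column coordinates: columns of domain B are offset by the original width
#' of domain A.
#'
#' @param msa_a,msa_b Domain alignments sharing ordered sequence ids.
#' @param params [pseudocount_params()].
#' @param top_n Number of top-ranked pairs to report (default 24;
#'   `Inf` reports all).
#' @param max_gap_fraction Gap-filter threshold (default 0.30).
#' @param min_separation Minimum intra-domain column separation (default 5).
#' @param weights `NULL`, a numeric vector of per-row weights, or a fractional
#'   identity threshold in `(0, 1)` to compute [msa_weights()] on the
#'   concatenated alignment.
#' @param rank_by `"mip"` (default) or `"mi"`.
#' @param label_a,label_b Domain names.
#' @return A `coevolution_result`; see [tidy.coevolution_result()].
#' @export
predict_coevolving_pairs <- function(msa_a, msa_b,
                                     params = pseudocount_params(),
                                     top_n = 24, max_gap_fraction = 0.30,
                                     min_separation = 5, weights = NULL,
                                     rank_by = c("mip", "mi"),
                                     label_a = "A", label_b = "B") {
  rank_by <- match.arg(rank_by)
  fa <- remove_gappy_columns(msa_a, max_gap_fraction)
  fb <- remove_gappy_columns(msa_b, max_gap_fraction)
  cc <- concatenate_alignments(fa$msa, fb$msa, label_a, label_b)
  boundary <- cc$partition$boundary
  # filtered concatenated column -> original concatenated column
  column_map <- c(fa$column_map, msa_a$n_cols + fb$column_map)
  if (is.numeric(weights) && length(weights) == 1 && weights > 0 && weights < 1) {
    weights <- msa_weights(cc$msa, identity_threshold = weights)
  }
  ap <- mi_all_pairs(cc$msa, params, weights)
  mip <- apc_correction(ap$mi)
  L <- ncol(ap$mi)
  idx <- which(upper.tri(ap$mi), arr.ind = TRUE)
  pairs <- tibble(
    fi = idx[, 1], fj = idx[, 2],
    i = column_map[idx[, 1]], j = column_map[idx[, 2]],
    MI = ap$mi[idx], MIp = mip[idx],
    neff = ap$neff[idx]
  ) %>%
    mutate(class = dplyr::case_when(
      .data$fi <= boundary & .data$fj > boundary ~ "inter",
      .data$fj <= boundary ~ paste0("intra_", label_a),
      TRUE ~ paste0("intra_", label_b)
    )) %>%
    filter(!is.na(.data$MI))
  # suppress trivial chain neighbours within a domain (original coordinates)
  pairs <- pairs %>%
    filter(.data$class == "inter" | abs(.data$j - .data$i) >= min_separation)
  key <- if (rank_by == "mip") pairs$MIp else pairs$MI
  ord <- order(-key, -pairs$MI, pairs$i, pairs$j)
  pairs <- pairs[ord, , drop = FALSE] %>%
    mutate(rank = row_number()) %>%
    select("i", "j", "MI", "MIp", "rank", "class", "neff")
  structure(
    list(
      pairs = head(pairs, n = if (is.finite(top_n)) top_n else nrow(pairs)),
      all_pairs = pairs,
      partition = cc$partition,
      boundary_original = msa_a$n_cols,
      column_map = column_map,
      params = params,
      n_seqs = length(msa_a$ids),
      rank_by = rank_by
    ),
    class = "coevolution_result"
  )
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf(
    "<coevolution_result> %d sequences, %d retained columns (boundary %d)\n",
    x$n_seqs, length(x$column_map), x$partition$boundary))
  print(x$pairs, n = 10)
  invisible(x)
}

#' Tidy a co-evolution result
#'
#' @param x A `coevolution_result`.
#' @param all Return all scored pairs instead of the reported top set.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (original concatenated column
#'   positions), `MI`, `MIp`, `rank`, `class`, `neff`.
#' @export
tidy.coevolution_result <- function(x, all = FALSE, ...) {
  if (all) x$all_pairs else x$pairs
}

#' One-row summary of a co-evolution result
#'
#' @param x A `coevolution_result`.
#' @param ... Unused.
#' @return Tibble with pair counts by class and the top MIp score.
#' @export
glance.coevolution_result <- function(x, ...) {
  p <- x$pairs
  tibble(
    n_seqs = x$n_seqs,
    n_columns = length(x$column_map),
    n_pairs_reported = nrow(p),
    n_inter = sum(p$class == "inter"),
    n_intra_a = sum(startsWith(p$class, "intra_") &
                      p$class == paste0("intra_", x$partition$label_a)),
    n_intra_b = sum(p$class == paste0("intra_", x$partition$label_b)),
    top_mip = if (nrow(p)) max(p$MIp) else NA_real_
  )
}
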