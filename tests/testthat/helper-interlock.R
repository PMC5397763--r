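# Shared builders for synthetic structures and abstract networks.

# Snapshot whose residue interaction network is exactly a requested edge list.
# Residues sit on one chain with resno spaced 10 apart (the covalent-neighbour
# exclusion never triggers) and CA atoms 100 A apart. Each requested edge
# (i, j, n_contacts) gets n_contacts dedicated atom pairs 3 A apart, each pair
# in its own slot 20 A from every other slot, so the heavy-atom contact count
# of a residue pair equals exactly the requested n_contacts. With the
# normalization constant ALA = 100 (see unit_params()) the percentage
# interaction strength of a pair equals its contact count.
make_contact_snapshot <- function(n_res, edges = NULL) {
  resno <- 10L * seq_len(n_res)
  rows <- lapply(seq_len(n_res), function(i) {
    list(resno = resno[i], name = "CA", xyz = c(100 * i, 0, 0))
  })
  counter <- integer(n_res)
  slot <- 0
  if (!is.null(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k]; j <- edges$j[k]
      for (m in seq_len(edges$n_contacts[k])) {
        slot <- slot + 1
        p <- c(20 * slot, 1000, 0)
        counter[i] <- counter[i] + 1
        rows[[length(rows) + 1]] <- list(resno = resno[i],
                                         name = sprintf("C%d", counter[i]),
                                         xyz = p)
        counter[j] <- counter[j] + 1
        rows[[length(rows) + 1]] <- list(resno = resno[j],
                                         name = sprintf("C%d", counter[j]),
                                         xyz = p + c(3, 0, 0))
      }
    }
  }
  ord <- order(vapply(rows, function(r) r$resno, numeric(1)))
  rows <- rows[ord]
  atoms <- interlock:::new_atoms_tibble(
    chain = "A",
    resno = vapply(rows, function(r) r$resno, numeric(1)),
    insert = "",
    resname = "ALA",
    atom_name = vapply(rows, function(r) r$name, character(1)),
    element = "C"
  )
  snapshot(atoms, do.call(rbind, lapply(rows, function(r) r$xyz)))
}

# network parameters under which strength(%) == n_contacts for ALA residues
unit_params <- function(i_min = 0.5) {
  network_params(i_min = i_min, normalization = c(ALA = 100))
}

# residue_network with arbitrary topology, bypassing geometry entirely
# (edge_df: data frame with columns i, j and optionally strength)
abstract_network <- function(n, edge_df) {
  strength <- if ("strength" %in% names(edge_df)) edge_df$strength
              else rep(5, nrow(edge_df))
  structure(
    list(
      nodes = tibble::tibble(node_id = sprintf("A:%d", seq_len(n))),
      edges = tibble::tibble(
        node_i = sprintf("A:%d", edge_df$i),
        node_j = sprintf("A:%d", edge_df$j),
        strength = strength,
        n_contacts = rep(1L, nrow(edge_df))
      ),
      params = network_params()
    ),
    class = "residue_network"
  )
}

# displace all pseudo side-chain atoms of one residue far away in a copy of
# a coordinate matrix (used to delete that residue's network edges per frame)
detach_residue <- function(snap, node_id, offset = c(0, 0, 1e4)) {
  at <- snap$atoms
  idx <- which(at$node_id == node_id & at$atom_name != "CA")
  m <- snap$xyz
  m[idx, ] <- m[idx, ] + matrix(offset, nrow = length(idx), ncol = 3,
                                byrow = TRUE)
  m
}

# the standard planted toy complex used across structural tests
demo_spec <- function() {
  toy_complex_spec(
    n_res_a = 12, n_res_b = 12,
    contact_pairs = list(c(3, 4), c(6, 7)),
    hbond_pairs = list(c(3, 4)),
    path_chain = c(2, 5, 8, 11)
  )
}

# independent Kabsch oracle: minimal RMSD fitting A onto B (rows = atoms)
kabsch_oracle_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  s <- svd(t(A0) %*% B0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- A0 %*% t(R)
  sqrt(mean(rowSums((fit - B0)^2)))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
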