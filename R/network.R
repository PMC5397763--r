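# Residue interaction networks.
#
# Nodes are residues; the interaction strength of a residue pair is the
# percentage I = 100 * n_ij / sqrt(N_i * N_j), where n_ij counts heavy-atom
# pairs (one atom from each residue) within the contact cutoff and N_i, N_j
# are per-residue-type normalization constants. Edges are kept when the
# strength reaches the I_min cutoff; covalent neighbours (small intra-chain
# sequence separation) are excluded so paths reflect non-covalent contacts.

#' Residue-network construction parameters
#'
#' @param contact_cutoff Heavy-atom contact distance cutoff (A, default 4.5).
#' @param i_min Percentage interaction-strength cutoff for edges
#'   (default 2.5).
#' @param exclude_neighbors Intra-chain sequence separation at or below which
#'   edges are dropped (default 2).
#' @param normalization Named numeric vector of per-residue-type
#'   normalization constants (default [psn_normalization()]).
#' @return A `network_params` list.
#' @export
network_params <- function(contact_cutoff = 4.5, i_min = 2.5,
                           exclude_neighbors = 2,
                           normalization = psn_normalization()) {
  if (contact_cutoff <= 0 || i_min < 0) {
    stop_interlock("contact_cutoff must be > 0 and i_min >= 0",
                   "interlock_spec_error")
  }
  structure(
    list(contact_cutoff = contact_cutoff, i_min = i_min,
         exclude_neighbors = exclude_neighbors, normalization = normalization),
    class = "network_params"
  )
}

# all residue pairs with at least one heavy-atom contact; strengths in %,
# covalent neighbours already excluded
pair_strengths <- function(snap, params) {
  at <- snap$atoms
  heavy <- at$element != "H"
  xyz <- snap$xyz[heavy, , drop = FALSE]
  res <- at$res_index[heavy]
  norm <- params$normalization
  rtab <- residues(at)
  nconst <- norm[rtab$resname]
  if (anyNA(nconst)) {
    bad <- unique(rtab$resname[is.na(nconst)])
    stop_interlock(
      sprintf("no normalization constant for residue type(s): %s",
              paste(bad, collapse = ", ")),
      "interlock_config_error"
    )
  }
  d <- as.matrix(dist(xyz))
  contact <- d <= params$contact_cutoff
  contact[lower.tri(contact, diag = TRUE)] <- FALSE
  idx <- which(contact, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble(res_i = integer(), res_j = integer(),
                  n_contacts = integer(), strength = numeric()))
  }
  ri <- pmin(res[idx[, 1]], res[idx[, 2]])
  rj <- pmax(res[idx[, 1]], res[idx[, 2]])
  keep <- ri != rj
  ri <- ri[keep]; rj <- rj[keep]
  if (!length(ri)) {
    return(tibble(res_i = integer(), res_j = integer(),
                  n_contacts = integer(), strength = numeric()))
  }
  tab <- tibble(res_i = ri, res_j = rj) %>%
    count(.data$res_i, .data$res_j, name = "n_contacts")
  same_chain <- rtab$chain[tab$res_i] == rtab$chain[tab$res_j]
  sep <- abs(rtab$resno[tab$res_i] - rtab$resno[tab$res_j])
  tab <- tab[!(same_chain & sep <= params$exclude_neighbors), , drop = FALSE]
  tab$strength <- as.numeric(100 * tab$n_contacts /
                               sqrt(nconst[tab$res_i] * nconst[tab$res_j]))
  tab
}

#' Percentage interaction strength of a residue pair
#'
#' @param snap A [snapshot()].
#' @param res_i,res_j Residue identifiers (`"chain:resno"`).
#' @param params [network_params()] (the `i_min` cutoff is not applied here).
#' @return Percentage interaction strength (0 when no heavy-atom contacts).
#' @export
interaction_strength <- function(snap, res_i, res_j,
                                 params = network_params()) {
  stopifnot(inherits(snap, "snapshot"))
  ia <- resolve_residue(snap, res_i)
  ib <- resolve_residue(snap, res_j)
  at <- snap$atoms
  heavy_i <- which(at$res_index == ia & at$element != "H")
  heavy_j <- which(at$res_index == ib & at$element != "H")
  di <- snap$xyz[heavy_i, , drop = FALSE]
  dj <- snap$xyz[heavy_j, , drop = FALSE]
  d2 <- outer(rowSums(di^2), rowSums(dj^2), "+") - 2 * di %*% t(dj)
  n_ij <- sum(d2 <= params$contact_cutoff^2 + 1e-12)
  norm <- params$normalization
  rt <- residues(at)
  ni <- norm[rt$resname[ia]]; nj <- norm[rt$resname[ib]]
  if (anyNA(c(ni, nj))) {
    stop_interlock("no normalization constant for residue type",
                   "interlock_config_error")
  }
  unname(100 * n_ij / sqrt(ni * nj))
}

#' Build a residue interaction network from one snapshot
#'
#' @param snap A [snapshot()].
#' @param params [network_params()]; edges with strength >= `params$i_min`
#'   are kept.
#' @return A `residue_network`: list with `nodes` (per-residue tibble) and
#'   `edges` (tibble `node_i`, `node_j`, `strength`, `n_contacts`).
#' @export
build_network <- function(snap, params = network_params()) {
  stopifnot(inherits(snap, "snapshot"))
  nodes <- residues(snap)
  ps <- pair_strengths(snap, params)
  ps <- ps[ps$strength >= params$i_min, , drop = FALSE]
  edges <- tibble(
    node_i = nodes$node_id[ps$res_i],
    node_j = nodes$node_id[ps$res_j],
    strength = ps$strength,
    n_contacts = ps$n_contacts
  )
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("<residue_network> %d nodes, %d edges (i_min %.2f%%)\n",
              nrow(x$nodes), nrow(x$edges), x$params$i_min))
  invisible(x)
}

#' @export
tidy.residue_network <- function(x, ...) x$edges

# igraph view of a residue_network (all residues as vertices)
network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("node_i", "node_j")],
    directed = FALSE,
    vertices = net$nodes$node_id
  )
}

#' Largest-cluster size along an interaction-strength grid
#'
#' For each candidate `I_min`, keeps edges at or above that strength and
#' records the size of the largest connected component; the profile is
#' non-increasing along the grid and its sharpest drop locates the
#' interaction-strength transition used to calibrate `I_min`.
#'
#' @param snap A [snapshot()].
#' @param i_min_grid Strictly increasing percentage grid (default 0 to 10 in
#'   0.5 steps).
#' @param params [network_params()] (its `i_min` is ignored here).
#' @return Tibble with `i_min` and `largest_cluster`.
#' @export
largest_cluster_profile <- function(snap,
                                    i_min_grid = seq(0, 10, by = 0.5),
                                    params = network_params()) {
  if (!length(i_min_grid)) {
    stop_interlock("i_min grid is empty", "interlock_spec_error")
  }
  if (any(diff(i_min_grid) <= 0)) {
    stop_interlock("i_min grid must be strictly increasing", "interlock_spec_error")
  }
  nodes <- residues(snap)
  ps <- pair_strengths(snap, params)
  sizes <- vapply(i_min_grid, function(v) {
    keep <- ps$strength >= v
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes$node_id[ps$res_i[keep]],
                 to = nodes$node_id[ps$res_j[keep]]),
      directed = FALSE, vertices = nodes$node_id
    )
    max(igraph::components(g)$csize)
  }, numeric(1))
  tibble(i_min = i_min_grid, largest_cluster = sizes)
}

#' Select I_min at the largest-cluster transition
#'
#' Returns the grid value at which the drop in largest-component size from
#' the previous grid point is maximal (first such value on ties). When the
#' profile is constant there is no transition and `transition_found` is
#' `FALSE`; callers usually fall back to the conventional default of 2.5%.
#'
#' @param profile Output of [largest_cluster_profile()].
#' @return List with `i_min` (`NA` when no transition), `drop`, and
#'   `transition_found`.
#' @export
select_imin <- function(profile) {
  if (!nrow(profile)) {
    stop_interlock("empty cluster profile", "interlock_spec_error")
  }
  drops <- -diff(profile$largest_cluster)
  if (!length(drops) || all(drops <= 0)) {
    return(list(i_min = NA_real_, drop = 0, transition_found = FALSE))
  }
  k <- which.max(drops)   # first maximum
  list(i_min = profile$i_min[k + 1], drop = drops[k], transition_found = TRUE)
}

#' Dynamically stable network over an ensemble
#'
#' Builds the per-frame network at `params$i_min` in every frame, computes
#' each edge's frequency (fraction of frames in which it is present), and
#' keeps edges whose frequency is at least `stability` (inclusive).
#'
#' @param ens An [ensemble()].
#' @param params [network_params()].
#' @param stability Dynamic-stability cutoff in `[0, 1]` (default 0.5).
#' @return An `ensemble_network`: list with `per_frame` (list of
#'   `residue_network`), `edge_frequency` (tibble with `node_i`, `node_j`,
#'   `frequency`, `mean_strength`, `stable`), `stable_edges`, and a
#'   `stable_network` (a `residue_network` of the stable edges).
#' @export
stable_network <- function(ens, params = network_params(), stability = 0.5) {
  stopifnot(inherits(ens, "ensemble"))
  nets <- lapply(seq_len(n_frames(ens)), function(f) {
    build_network(get_snapshot(ens, f), params)
  })
  all_edges <- bind_rows(lapply(nets, `[[`, "edges"))
  nfr <- length(nets)
  freq <- all_edges %>%
    group_by(.data$node_i, .data$node_j) %>%
    summarise(frequency = dplyr::n() / nfr,
              mean_strength = mean(.data$strength), .groups = "drop") %>%
    mutate(stable = .data$frequency >= stability) %>%
    arrange(dplyr::desc(.data$frequency))
  stable_edges <- freq %>% filter(.data$stable)
  stable_net <- structure(
    list(
      nodes = nets[[1]]$nodes,
      edges = stable_edges %>%
        mutate(strength = .data$mean_strength) %>%
        select("node_i", "node_j", "strength"),
      params = params
    ),
    class = "residue_network"
  )
  structure(
    list(per_frame = nets, edge_frequency = freq, stable_edges = stable_edges,
         stable_network = stable_net, stability = stability, params = params),
    class = "ensemble_network"
  )
}

#' @export
print.ensemble_network <- function(x, ...) {
  cat(sprintf(
    "<ensemble_network> %d frames, %d distinct edges, %d stable (>= %.0f%%)\n",
    length(x$per_frame), nrow(x$edge_frequency), nrow(x$stable_edges),
    100 * x$stability))
  invisible(x)
}

#' @export
tidy.ensemble_network <- function(x, ...) x$edge_frequency
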