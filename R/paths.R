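# Communication paths on residue networks.
#
# All-pairs shortest paths are computed with the Floyd-Warshall algorithm on
# unweighted (hop-count) edges; a path is reconstructed greedily from the
# distance matrix, preferring at every step the smallest node in the
# network's canonical residue order (chain, then residue number), which makes
# tie-breaking deterministic. A strength-weighted mode is available where
# edge cost is 1/strength.

# Floyd-Warshall distance matrix (vectorised over k)
floyd_warshall <- function(adj) {
  d <- adj
  n <- nrow(d)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    upd <- dk < d
    d[upd] <- dk[upd]
  }
  d
}

# adjacency cost matrix of a residue_network
network_cost_matrix <- function(net, weighted = FALSE) {
  ids <- net$nodes$node_id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  if (nrow(net$edges)) {
    i <- match(net$edges$node_i, ids)
    j <- match(net$edges$node_j, ids)
    w <- if (weighted) 1 / net$edges$strength else rep(1, length(i))
    d[cbind(i, j)] <- pmin(d[cbind(i, j)], w)
    d[cbind(j, i)] <- d[cbind(i, j)]
  }
  d
}

#' Shortest communication path between two residues
#'
#' Minimal hop-count path on the network via Floyd-Warshall with
#' deterministic reconstruction: among equally short continuations the
#' smallest node in canonical residue order is preferred.
#'
#' @param net A `residue_network` (see [build_network()]).
#' @param source,sink Residue identifiers (`"chain:resno"`).
#' @param weighted Use edge cost `1/strength` instead of hop counts.
#' @return Character vector of node ids from source to sink, or `NULL` when
#'   no path exists.
#' @export
shortest_path <- function(net, source, sink, weighted = FALSE) {
  ids <- net$nodes$node_id
  if (!source %in% ids || !sink %in% ids) {
    stop_interlock(sprintf("source/sink not in network: %s",
                           paste(setdiff(c(source, sink), ids), collapse = ", ")),
                   "interlock_lookup_error")
  }
  d <- floyd_warshall(network_cost_matrix(net, weighted))
  reconstruct_path(net, d, source, sink, weighted)
}

# greedy reconstruction from the FW distance matrix; adj must be the cost
# matrix d was computed from
reconstruct_path <- function(net, d, source, sink, weighted = FALSE) {
  ids <- net$nodes$node_id
  s <- match(source, ids); t <- match(sink, ids)
  if (!is.finite(d[s, t])) return(NULL)
  adj <- network_cost_matrix(net, weighted)
  path <- s
  u <- s
  eps <- 1e-9
  while (u != t) {
    nb <- which(is.finite(adj[u, ]) & adj[u, ] > 0)
    cand <- nb[abs(adj[u, nb] + d[nb, t] - d[u, t]) < eps]
    if (!length(cand)) return(NULL)  # defensive; cannot happen on a valid d
    u <- min(cand)                   # canonical residue order = node index order
    path <- c(path, u)
  }
  ids[path]
}

#' Shortest paths between residues over an ensemble
#'
#' Builds the residue network in every frame, extracts the shortest
#' source-to-sink path per frame, and summarises: the average path length
#' (hops, over frames with a path), the consensus nodes (residues present in
#' at least `consensus` of the per-frame paths), and the path on the
#' dynamically stable network.
#'
#' @param ens An [ensemble()].
#' @param source,sink Residue identifiers.
#' @param params [network_params()].
#' @param stability Dynamic-stability cutoff for the stable-network path.
#' @param consensus Fraction of per-frame paths a node must appear in to be a
#'   consensus node (default 0.5).
#' @param weighted Use strength-weighted edge costs.
#' @return A `path_result`: list with `per_frame` tibble (`frame`, `found`,
#'   `length`, `path`), `per_frame_paths` (list of node vectors),
#'   `average_length`, `consensus_nodes`, `stable_path`, `source`, `sink`.
#' @export
ensemble_paths <- function(ens, source, sink, params = network_params(),
                           stability = 0.5, consensus = 0.5,
                           weighted = FALSE) {
  stopifnot(inherits(ens, "ensemble"))
  en <- stable_network(ens, params, stability)
  paths <- lapply(en$per_frame, function(net) {
    shortest_path(net, source, sink, weighted)
  })
  found <- !vapply(paths, is.null, logical(1))
  lens <- ifelse(found, vapply(paths, length, integer(1)) - 1L, NA_integer_)
  per_frame <- tibble(
    frame = seq_along(paths),
    found = found,
    length = lens,
    path = vapply(paths, function(p) paste(p, collapse = " -> "), character(1))
  )
  avg <- if (any(found)) mean(lens[found]) else NA_real_
  cons <- character()
  if (any(found)) {
    tab <- table(unlist(paths[found]))
    cons <- sort(names(tab)[tab / sum(found) >= consensus])
  }
  stable_path <- tryCatch(
    shortest_path(en$stable_network, source, sink, weighted),
    interlock_error = function(e) NULL
  )
  structure(
    list(source = source, sink = sink, per_frame = per_frame,
         per_frame_paths = paths, average_length = avg,
         consensus_nodes = cons, stable_path = stable_path,
         consensus = consensus, ensemble_network = en),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result> %s -> %s: average length %s over %d/%d frames\n",
              x$source, x$sink,
              ifelse(is.na(x$average_length), "NA",
                     sprintf("%.2f", x$average_length)),
              sum(x$per_frame$found), nrow(x$per_frame)))
  if (length(x$consensus_nodes)) {
    cat("consensus:", paste(x$consensus_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.path_result <- function(x, ...) x$per_frame

#' @export
glance.path_result <- function(x, ...) {
  tibble(
    source = x$source, sink = x$sink,
    n_frames = nrow(x$per_frame),
    n_with_path = sum(x$per_frame$found),
    average_length = x$average_length,
    n_consensus_nodes = length(x$consensus_nodes),
    stable_path_length = if (is.null(x$stable_path)) NA_integer_
                         else length(x$stable_path) - 1L
  )
}

#' Residues common to several communication paths
#'
#' Intersection of the consensus nodes of two or more [ensemble_paths()]
#' results, with all sources and sinks excluded — the shared intermediates
#' through which every communication route passes.
#'
#' @param results List of `path_result` objects (>= 2).
#' @return Character vector of residue identifiers (possibly empty).
#' @export
common_path_residues <- function(results) {
  if (length(results) < 2) {
    stop_interlock("need at least two path results", "interlock_spec_error")
  }
  cons <- lapply(results, `[[`, "consensus_nodes")
  common <- Reduce(intersect, cons)
  ends <- unique(unlist(lapply(results, function(r) c(r$source, r$sink))))
  sort(setdiff(common, ends))
}
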