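# Synthetic two-chain complexes with known interface contacts, hydrogen
# bonds and communication paths.
#
# Layout (deterministic): both chains are straight C-alpha traces with 3.8 A
# consecutive spacing, chain A along y = 0 and chain B along y = 20 (so
# non-contact cross-chain residues are >= 8 A apart by construction).
# Each planted interaction occupies its own "slot" along x:
#   * contact pairs: a 3-atom pseudo side-chain cluster on each partner,
#     facing each other across the interface at ~3.0-3.1 A;
#   * hydrogen-bond pairs: the leading cluster atoms are a Lys NZ donor and
#     an Asp OD1 acceptor at 3.0 A;
#   * path links: the same cluster construction between consecutive
#     path residues, placed on the far side of the chain (y < 0) so they
#     never touch the interface.
# Slots are 12 A apart, so no unintended residue pair comes within contact
# range; every planted geometry is exact, which gives downstream analyses
# closed-form ground truth.

sc_name_pool <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CJ", "CK", "CL")

#' Specify a synthetic two-chain complex
#'
#' @param n_res_a,n_res_b Residue counts of chains A and B.
#' @param contact_pairs List of length-2 integer vectors `c(res_in_A,
#'   res_in_B)` (or a 2-column matrix) to be placed within interface distance
#'   (min cross-chain heavy-atom distance <= 4.5 A).
#' @param hbond_pairs Subset of `contact_pairs` to be given donor/acceptor
#'   geometry (Lys NZ - Asp OD1 at 3.0 A). Each residue may take part in at
#'   most one hydrogen-bond pair.
#' @param path_chain Optional ordered integer vector of residues forming a
#'   chain of mutual contacts (a planted communication path) within
#'   `path_chain_id`. Consecutive members should be more than 2 apart in
#'   sequence so the planted edges survive the default covalent-neighbour
#'   exclusion of [network_params()].
#' @param path_chain_id Chain carrying the planted path, `"A"` (default) or
#'   `"B"`.
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_res_a, n_res_b, contact_pairs = list(),
                             hbond_pairs = list(), path_chain = NULL,
                             path_chain_id = "A") {
  norm_pairs <- function(x) {
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    lapply(x, function(p) as.integer(p[1:2]))
  }
  contact_pairs <- norm_pairs(contact_pairs)
  hbond_pairs <- norm_pairs(hbond_pairs)
  for (p in contact_pairs) {
    if (p[1] < 1 || p[1] > n_res_a || p[2] < 1 || p[2] > n_res_b) {
      stop_interlock("contact residue outside chain range", "interlock_spec_error")
    }
  }
  key <- function(p) paste(p, collapse = "-")
  ck <- vapply(contact_pairs, key, character(1))
  for (p in hbond_pairs) {
    if (!key(p) %in% ck) {
      stop_interlock("hbond_pairs must be a subset of contact_pairs",
                     "interlock_spec_error")
    }
  }
  hb_a <- vapply(hbond_pairs, `[`, integer(1), 1)
  hb_b <- vapply(hbond_pairs, `[`, integer(1), 2)
  if (anyDuplicated(hb_a) || anyDuplicated(hb_b)) {
    stop_interlock("a residue may take part in at most one hbond pair",
                   "interlock_spec_error")
  }
  if (!is.null(path_chain)) {
    path_chain <- as.integer(path_chain)
    n_max <- if (path_chain_id == "A") n_res_a else n_res_b
    if (length(path_chain) < 2 || any(path_chain < 1 | path_chain > n_max)) {
      stop_interlock("path_chain residues outside chain range",
                     "interlock_spec_error")
    }
    if (anyDuplicated(path_chain)) {
      stop_interlock("path_chain residues must be distinct", "interlock_spec_error")
    }
  }
  structure(
    list(n_res_a = as.integer(n_res_a), n_res_b = as.integer(n_res_b),
         contact_pairs = contact_pairs, hbond_pairs = hbond_pairs,
         path_chain = path_chain, path_chain_id = path_chain_id),
    class = "toy_complex_spec"
  )
}

#' Generate a toy two-chain complex snapshot
#'
#' Places the complex described by a [toy_complex_spec()]; see the spec's
#' documentation for the geometric guarantees (planted contacts <= 4.5 A,
#' hydrogen bonds at 3.0 A, non-contact cross-chain residues >= 8 A apart).
#'
#' @param spec A [toy_complex_spec()].
#' @param seed Integer seed (layout is deterministic; kept for API symmetry
#'   with the other generators).
#' @return A [snapshot()] with attribute `interface_normal = c(0, 1, 0)`.
#' @export
generate_toy_complex <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(as.integer(seed))
  ca_gap <- 3.8
  chain_y <- c(A = 0, B = 20)
  # per-residue extra atoms, keyed "chain:res"
  extras <- list()
  resname <- list(
    A = rep("ALA", spec$n_res_a),
    B = rep("ALA", spec$n_res_b)
  )
  add_atom <- function(chain, res, name, element, x, y, z) {
    k <- paste0(chain, ":", res)
    extras[[k]] <<- c(extras[[k]], list(list(
      name = name, element = element, xyz = c(x, y, z)
    )))
  }
  next_c_name <- function(chain, res) {
    k <- paste0(chain, ":", res)
    used <- vapply(extras[[k]] %||% list(), `[[`, character(1), "name")
    nm <- setdiff(sc_name_pool, used)
    if (!length(nm)) {
      stop_interlock("too many pseudo-atoms requested for one residue",
                     "interlock_geometry_error")
    }
    nm[[1]]
  }
  hb_key <- vapply(spec$hbond_pairs, function(p) paste(p, collapse = "-"),
                   character(1))
  # interface slots (y between the chains)
  for (k in seq_along(spec$contact_pairs)) {
    p <- spec$contact_pairs[[k]]
    xk <- (k - 1) * 12
    is_hb <- paste(p, collapse = "-") %in% hb_key
    zs <- c(-0.4, 0, 0.4)
    for (s in seq_along(zs)) {
      if (is_hb && s == 1) {
        resname$A[p[1]] <- "LYS"; resname$B[p[2]] <- "ASP"
        add_atom("A", p[1], "NZ", "N", xk, 8.5, zs[s])
        add_atom("B", p[2], "OD1", "O", xk, 11.5, zs[s])
      } else {
        add_atom("A", p[1], next_c_name("A", p[1]), "C", xk, 8.5, zs[s])
        add_atom("B", p[2], next_c_name("B", p[2]), "C", xk, 11.5, zs[s])
      }
    }
  }
  # path-link slots (y on the far side of the carrying chain)
  if (!is.null(spec$path_chain)) {
    pc <- spec$path_chain
    ch <- spec$path_chain_id
    base_y <- chain_y[[ch]]
    sgn <- if (ch == "A") -1 else 1
    for (t in seq_len(length(pc) - 1)) {
      xt <- (t - 1) * 12
      for (z in c(-0.4, 0, 0.4)) {
        add_atom(ch, pc[t], next_c_name(ch, pc[t]), "C",
                 xt, base_y + sgn * 8.5, z)
        add_atom(ch, pc[t + 1], next_c_name(ch, pc[t + 1]), "C",
                 xt, base_y + sgn * 11.5, z)
      }
    }
  }
  # assemble atom table
  rows <- list()
  xyz <- list()
  for (ch in c("A", "B")) {
    n_res <- if (ch == "A") spec$n_res_a else spec$n_res_b
    for (r in seq_len(n_res)) {
      rows[[length(rows) + 1]] <- list(ch, r, resname[[ch]][r], "CA", "C")
      xyz[[length(xyz) + 1]] <- c((r - 1) * ca_gap, chain_y[[ch]], 0)
      for (a in extras[[paste0(ch, ":", r)]] %||% list()) {
        rows[[length(rows) + 1]] <- list(ch, r, resname[[ch]][r], a$name, a$element)
        xyz[[length(xyz) + 1]] <- a$xyz
      }
    }
  }
  atoms <- new_atoms_tibble(
    chain = vapply(rows, `[[`, character(1), 1),
    resno = vapply(rows, `[[`, numeric(1), 2),
    insert = "",
    resname = vapply(rows, `[[`, character(1), 3),
    atom_name = vapply(rows, `[[`, character(1), 4),
    element = vapply(rows, `[[`, character(1), 5)
  )
  snap <- snapshot(atoms, do.call(rbind, xyz))
  attr(snap, "interface_normal") <- c(0, 1, 0)
  attr(snap, "spec") <- spec
  snap
}

#' Perturb a base snapshot into a synthetic ensemble
#'
#' Each frame is the base structure plus i.i.d. isotropic Gaussian
#' displacement per atom. In a contiguous block of `round(broken_fraction *
#' n_frames)` frames (the final frames, or scattered when `scatter_broken`),
#' chain B is rigidly translated `break_distance` A along the interface
#' normal, which breaks all cross-chain contacts.
#'
#' @param base A [snapshot()] (typically from [generate_toy_complex()]).
#' @param n_frames Number of frames (>= 1).
#' @param noise_sd Gaussian displacement standard deviation (A, per
#'   coordinate).
#' @param broken_fraction Fraction of frames with the interface separated.
#' @param seed Integer seed; reproducible.
#' @param scatter_broken Scatter broken frames randomly instead of using a
#'   contiguous final block.
#' @param broken_chain Chain translated in broken frames.
#' @param break_distance Rigid translation distance (A).
#' @param normal Interface normal direction (default from the base snapshot's
#'   `interface_normal` attribute, else `c(0, 1, 0)`).
#' @param frame_spacing Frame spacing metadata (ps).
#' @return An [ensemble()] with attribute `broken_frames` (integer vector).
#' @export
generate_ensemble <- function(base, n_frames, noise_sd = 0,
                              broken_fraction = 0, seed = 1,
                              scatter_broken = FALSE, broken_chain = "B",
                              break_distance = 20, normal = NULL,
                              frame_spacing = 1000) {
  stopifnot(inherits(base, "snapshot"))
  if (n_frames < 1) stop_interlock("n_frames must be >= 1", "interlock_spec_error")
  if (noise_sd < 0) stop_interlock("noise_sd must be >= 0", "interlock_spec_error")
  if (broken_fraction < 0 || broken_fraction > 1) {
    stop_interlock("broken_fraction must be in [0, 1]", "interlock_spec_error")
  }
  normal <- normal %||% attr(base, "interface_normal") %||% c(0, 1, 0)
  normal <- normal / sqrt(sum(normal^2))
  set.seed(as.integer(seed))
  n_broken <- round(broken_fraction * n_frames)
  broken <- if (n_broken == 0) {
    integer()
  } else if (scatter_broken) {
    sort(sample(n_frames, n_broken))
  } else {
    seq(n_frames - n_broken + 1, n_frames)
  }
  b_idx <- base$atoms$chain == broken_chain
  shift <- matrix(rep(break_distance * normal, each = sum(b_idx)), ncol = 3)
  frames <- lapply(seq_len(n_frames), function(f) {
    m <- base$xyz
    if (noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = noise_sd), ncol = 3)
    }
    if (f %in% broken) m[b_idx, ] <- m[b_idx, ] + shift
    m
  })
  out <- ensemble(base$atoms, frames, frame_spacing = frame_spacing)
  attr(out, "broken_frames") <- broken
  out
}

#' Write the planted ground truth of a toy complex as TSV
#'
#' @param spec A [toy_complex_spec()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_toy_truth <- function(spec, path) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  rows <- c("kind\tchain_a\tres_a\tchain_b\tres_b")
  for (p in spec$contact_pairs) {
    kind <- if (paste(p, collapse = "-") %in%
                vapply(spec$hbond_pairs, paste, character(1), collapse = "-"))
      "hbond_contact" else "contact"
    rows <- c(rows, sprintf("%s\tA\t%d\tB\t%d", kind, p[1], p[2]))
  }
  if (!is.null(spec$path_chain)) {
    rows <- c(rows, sprintf("path\t%s\t%s\t\t", spec$path_chain_id,
                            paste(spec$path_chain, collapse = ",")))
  }
  writeLines(rows, path)
  invisible(path)
}
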