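# Cross-chain interface characterisation: interface residues, hydrogen bonds
# and their occupancy over an ensemble, minimum-distance series, and
# distance-threshold pseudoenergies with hotspot identification.
#
# Pseudoenergies are simple counting scores with distance thresholds, not a
# physical force field: each detected hydrogen bond, electrostatic residue
# pair and van der Waals atom contact contributes a fixed configurable
# energy. Defaults are calibrated so a well-formed toy interface lands in the
# -2 to -3 kcal/mol normalized-per-residue range typical of stable
# protein-protein complexes.

#' Hydrogen-bond detection criteria
#'
#' Donor-acceptor heavy-atom distance, plus a hydrogen-donor-acceptor angle
#' criterion applied only when hydrogens are present in the structure.
#'
#' @param da_cutoff Donor-acceptor distance cutoff (A, default 3.5).
#' @param angle_cutoff Hydrogen-donor-acceptor angle cutoff (degrees,
#'   default 30).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, angle_cutoff = 30) {
  if (da_cutoff <= 0 || angle_cutoff <= 0) {
    stop_interlock("hbond cutoffs must be positive", "interlock_spec_error")
  }
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Interface pseudoenergy configuration
#'
#' @param e_hbond Energy per cross-chain hydrogen bond (kcal/mol).
#' @param e_elec Magnitude of the electrostatic term per charged residue pair
#'   within `elec_cutoff` (attractive, negative, for opposite formal charges;
#'   repulsive for like charges).
#' @param elec_cutoff Charged-group distance cutoff (A).
#' @param e_vdw Energy per cross-chain heavy-atom pair within `vdw_range`.
#' @param vdw_range Distance window (A) defining a van der Waals contact.
#' @param interface_cutoff Heavy-atom distance defining interface residues.
#' @param hotspot_threshold Per-residue energy at or below which a residue is
#'   a hotspot (kcal/mol).
#' @param criteria [hbond_criteria()] used for the hydrogen-bond term.
#' @return An `energy_config` list.
#' @export
energy_config <- function(e_hbond = -1.5, e_elec = 1.0, elec_cutoff = 6.0,
                          e_vdw = -0.2, vdw_range = c(3.0, 5.0),
                          interface_cutoff = 5.0, hotspot_threshold = -2.0,
                          criteria = hbond_criteria()) {
  structure(
    list(e_hbond = e_hbond, e_elec = e_elec, elec_cutoff = elec_cutoff,
         e_vdw = e_vdw, vdw_range = vdw_range,
         interface_cutoff = interface_cutoff,
         hotspot_threshold = hotspot_threshold, criteria = criteria),
    class = "energy_config"
  )
}

# heavy-atom coordinate/index helper for one chain
chain_heavy <- function(snap, chain) {
  at <- snap$atoms
  idx <- which(at$chain == chain & at$element != "H")
  if (!length(idx)) {
    stop_interlock(sprintf("chain %s not found (or has no heavy atoms)", chain),
                   "interlock_lookup_error")
  }
  idx
}

# cross-chain heavy-atom distance matrix (rows chain a, cols chain b)
cross_distances <- function(snap, ia, ib) {
  A <- snap$xyz[ia, , drop = FALSE]
  B <- snap$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Interface residues of a two-chain snapshot
#'
#' Residues of either chain with any heavy atom within `cutoff` of any heavy
#' atom of the other chain. Symmetric in the chain arguments.
#'
#' @param snap A [snapshot()].
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Heavy-atom distance cutoff (A, default 5.0).
#' @return Tibble with one row per interface residue: `node_id`, `chain`,
#'   `resno`, `resname`, `min_cross_distance`.
#' @export
interface_residues <- function(snap, chain_a = "A", chain_b = "B",
                               cutoff = 5.0) {
  stopifnot(inherits(snap, "snapshot"))
  ia <- chain_heavy(snap, chain_a)
  ib <- chain_heavy(snap, chain_b)
  d <- cross_distances(snap, ia, ib)
  at <- snap$atoms
  res_a <- at$res_index[ia]
  res_b <- at$res_index[ib]
  mins_a <- tapply(apply(d, 1, min), res_a, min)
  mins_b <- tapply(apply(d, 2, min), res_b, min)
  rtab <- residues(at)
  out <- bind_rows(
    tibble(res_index = as.integer(names(mins_a)),
           min_cross_distance = as.numeric(mins_a)),
    tibble(res_index = as.integer(names(mins_b)),
           min_cross_distance = as.numeric(mins_b))
  ) %>%
    filter(.data$min_cross_distance <= cutoff) %>%
    left_join(rtab, by = "res_index") %>%
    arrange(.data$res_index) %>%
    select("node_id", "chain", "resno", "resname", "min_cross_distance")
  out
}

# donor and acceptor heavy atoms of a snapshot
hbond_atom_roles <- function(snap) {
  at <- snap$atoms
  role <- mapply(hbond_role, at$resname, at$atom_name, USE.NAMES = FALSE)
  tibble(
    atom = seq_len(nrow(at)),
    donor = !is.na(role) & role %in% c("donor", "both"),
    acceptor = !is.na(role) & role %in% c("acceptor", "both")
  )
}

#' Detect hydrogen bonds in a snapshot
#'
#' All donor/acceptor heavy-atom pairs (standard N/O roles by residue type)
#' within the distance cutoff; when hydrogen atoms are present, a hydrogen
#' bonded to the donor (within 1.2 A) must make a hydrogen-donor-acceptor
#' angle within the angle cutoff.
#'
#' @param snap A [snapshot()].
#' @param criteria [hbond_criteria()].
#' @param cross_chain_only Keep only bonds between different chains
#'   (default TRUE).
#' @return Tibble with one row per detected donor-acceptor atom pair:
#'   donor/acceptor residue ids, atom names and the distance.
#' @export
detect_hbonds <- function(snap, criteria = hbond_criteria(),
                          cross_chain_only = TRUE) {
  stopifnot(inherits(snap, "snapshot"))
  at <- snap$atoms
  roles <- hbond_atom_roles(snap)
  don <- which(roles$donor)
  acc <- which(roles$acceptor)
  empty <- tibble(
    donor_residue = character(), donor_atom = character(),
    acceptor_residue = character(), acceptor_atom = character(),
    distance = numeric()
  )
  if (!length(don) || !length(acc)) return(empty)
  D <- snap$xyz[don, , drop = FALSE]
  A <- snap$xyz[acc, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * D %*% t(A)
  hits <- which(d2 <= criteria$da_cutoff^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  di <- don[hits[, 1]]; ai <- acc[hits[, 2]]
  keep <- at$res_index[di] != at$res_index[ai]
  if (cross_chain_only) keep <- keep & (at$chain[di] != at$chain[ai])
  di <- di[keep]; ai <- ai[keep]
  if (!length(di)) return(empty)
  dist <- sqrt(pmax(d2[hits[keep, , drop = FALSE]], 0))
  # angle criterion: only when the donor has an attached hydrogen
  hyd <- which(at$element == "H")
  if (length(hyd)) {
    ok <- vapply(seq_along(di), function(k) {
      dpos <- snap$xyz[di[k], ]
      apos <- snap$xyz[ai[k], ]
      hres <- hyd[at$res_index[hyd] == at$res_index[di[k]]]
      if (!length(hres)) return(TRUE)
      hd <- sqrt(colSums((t(snap$xyz[hres, , drop = FALSE]) - dpos)^2))
      hres <- hres[hd <= 1.2]
      if (!length(hres)) return(TRUE)
      any(vapply(hres, function(h) {
        v1 <- snap$xyz[h, ] - dpos
        v2 <- apos - dpos
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
        ang * 180 / pi <= criteria$angle_cutoff
      }, logical(1)))
    }, logical(1))
    di <- di[ok]; ai <- ai[ok]; dist <- dist[ok]
  }
  tibble(
    donor_residue = at$node_id[di], donor_atom = at$atom_name[di],
    acceptor_residue = at$node_id[ai], acceptor_atom = at$atom_name[ai],
    distance = dist
  ) %>% arrange(.data$donor_residue, .data$acceptor_residue, .data$distance)
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' For every residue pair that is hydrogen-bonded in at least one frame,
#' occupancy is the fraction of frames in which the bond is present; a bond
#' is `stable` when its occupancy is strictly greater than 0.5.
#'
#' @param ens An [ensemble()].
#' @param criteria [hbond_criteria()].
#' @param cross_chain_only Keep only cross-chain bonds (default TRUE).
#' @return Tibble with `donor_residue`, `acceptor_residue`,
#'   `n_frames_present`, `occupancy`, `stable`.
#' @export
hbond_occupancy <- function(ens, criteria = hbond_criteria(),
                            cross_chain_only = TRUE) {
  stopifnot(inherits(ens, "ensemble"))
  nfr <- n_frames(ens)
  per_frame <- lapply(seq_len(nfr), function(f) {
    detect_hbonds(get_snapshot(ens, f), criteria, cross_chain_only) %>%
      distinct(.data$donor_residue, .data$acceptor_residue)
  })
  bind_rows(per_frame) %>%
    count(.data$donor_residue, .data$acceptor_residue,
          name = "n_frames_present") %>%
    mutate(occupancy = .data$n_frames_present / nfr,
           stable = .data$occupancy > 0.5) %>%
    arrange(dplyr::desc(.data$occupancy),
            .data$donor_residue, .data$acceptor_residue)
}

#' Minimum-distance series between two residues
#'
#' Per frame, the minimum over all heavy-atom pairs between the two residues.
#'
#' @param ens An [ensemble()].
#' @param pair Length-2 character vector of residue identifiers.
#' @return Tibble with `frame`, `time` (ps, when frame spacing is known) and
#'   `distance` (A).
#' @export
min_distance_series <- function(ens, pair) {
  stopifnot(inherits(ens, "ensemble"), length(pair) == 2)
  at <- ens$atoms
  ri <- resolve_residue(at, pair[1])
  rj <- resolve_residue(at, pair[2])
  ia <- which(at$res_index == ri & at$element != "H")
  ib <- which(at$res_index == rj & at$element != "H")
  dists <- vapply(seq_len(n_frames(ens)), function(f) {
    A <- ens$xyz[[f]][ia, , drop = FALSE]
    B <- ens$xyz[[f]][ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  tibble(
    frame = seq_along(dists),
    time = if (!is.null(ens$frame_spacing))
      (seq_along(dists) - 1) * ens$frame_spacing else NA_real_,
    distance = dists
  )
}

# all energy terms of a snapshot interface, one row per term with both
# participating residues (for totals and per-residue attribution)
interface_energy_terms <- function(snap, config = energy_config(),
                                   chain_a = "A", chain_b = "B") {
  at <- snap$atoms
  terms <- list()
  # hydrogen bonds (cross-chain donor-acceptor atom pairs)
  hb <- detect_hbonds(snap, config$criteria, cross_chain_only = TRUE)
  hb <- hb[substr(hb$donor_residue, 1, 1) %in% c(chain_a, chain_b) &
             substr(hb$acceptor_residue, 1, 1) %in% c(chain_a, chain_b), ,
           drop = FALSE]
  if (nrow(hb)) {
    terms[[length(terms) + 1]] <- tibble(
      type = "hbond", res_i = hb$donor_residue, res_j = hb$acceptor_residue,
      energy = config$e_hbond
    )
  }
  # electrostatics: charged residue groups within the cutoff
  chg <- mapply(formal_charge, at$resname, at$atom_name, USE.NAMES = FALSE)
  ca <- which(at$chain == chain_a & chg != 0)
  cb <- which(at$chain == chain_b & chg != 0)
  if (length(ca) && length(cb)) {
    d <- cross_distances(snap, ca, cb)
    # min distance between charged atoms per residue pair
    df <- tibble(
      res_i = at$node_id[ca[row(d)]], res_j = at$node_id[cb[col(d)]],
      qi = chg[ca[row(d)]], qj = chg[cb[col(d)]],
      dist = as.vector(d)
    ) %>%
      group_by(.data$res_i, .data$res_j, .data$qi, .data$qj) %>%
      summarise(dist = min(.data$dist), .groups = "drop") %>%
      filter(.data$dist <= config$elec_cutoff)
    if (nrow(df)) {
      terms[[length(terms) + 1]] <- tibble(
        type = "electrostatic", res_i = df$res_i, res_j = df$res_j,
        energy = ifelse(df$qi * df$qj < 0, -config$e_elec, config$e_elec)
      )
    }
  }
  # van der Waals: cross-chain heavy-atom pairs inside the window
  ia <- chain_heavy(snap, chain_a)
  ib <- chain_heavy(snap, chain_b)
  d <- cross_distances(snap, ia, ib)
  hits <- which(d >= config$vdw_range[1] & d <= config$vdw_range[2],
                arr.ind = TRUE)
  if (nrow(hits)) {
    terms[[length(terms) + 1]] <- tibble(
      type = "vdw",
      res_i = at$node_id[ia[hits[, 1]]],
      res_j = at$node_id[ib[hits[, 2]]],
      energy = config$e_vdw
    )
  }
  if (!length(terms)) {
    return(tibble(type = character(), res_i = character(),
                  res_j = character(), energy = numeric()))
  }
  bind_rows(terms)
}

#' Interface pseudoenergy breakdown of a snapshot
#'
#' Counting-based pseudoenergies with distance thresholds: hydrogen-bond,
#' electrostatic and van der Waals terms (see [energy_config()]), their sum,
#' the number of interface residues, and the total normalized per interface
#' residue.
#'
#' @param snap A [snapshot()].
#' @param config [energy_config()].
#' @param chain_a,chain_b Chain identifiers.
#' @return One-row tibble of class `energy_breakdown` with columns
#'   `hbond_energy`, `electrostatic_energy`, `vdw_energy`,
#'   `total_stabilizing`, `n_interface_residues`, `normalized_per_residue`
#'   (NA when the interface is empty).
#' @export
interface_energies <- function(snap, config = energy_config(),
                               chain_a = "A", chain_b = "B") {
  terms <- interface_energy_terms(snap, config, chain_a, chain_b)
  iface <- interface_residues(snap, chain_a, chain_b,
                              cutoff = config$interface_cutoff)
  tot <- function(t) sum(terms$energy[terms$type == t])
  hb <- tot("hbond"); el <- tot("electrostatic"); vd <- tot("vdw")
  n_if <- nrow(iface)
  out <- tibble(
    hbond_energy = hb, electrostatic_energy = el, vdw_energy = vd,
    total_stabilizing = hb + el + vd,
    n_interface_residues = n_if,
    normalized_per_residue = if (n_if > 0) (hb + el + vd) / n_if else NA_real_
  )
  class(out) <- c("energy_breakdown", class(out))
  attr(out, "terms") <- terms
  out
}

#' Interface energies along an ensemble
#'
#' Applies [interface_energies()] to every `stride`-th frame.
#'
#' @param ens An [ensemble()].
#' @param config [energy_config()].
#' @param chain_a,chain_b Chain identifiers.
#' @param stride Frame stride (>= 1).
#' @return Tidy tibble: one row per analysed frame with `frame`, `time` and
#'   the energy-breakdown columns.
#' @export
energy_time_series <- function(ens, config = energy_config(),
                               chain_a = "A", chain_b = "B", stride = 1) {
  stopifnot(inherits(ens, "ensemble"))
  if (stride < 1) stop_interlock("stride must be >= 1", "interlock_spec_error")
  frames <- seq(1, n_frames(ens), by = stride)
  rows <- lapply(frames, function(f) {
    snap <- get_snapshot(ens, f)
    eb <- interface_energies(snap, config, chain_a, chain_b)
    attr(eb, "terms") <- NULL
    dplyr::bind_cols(tibble(frame = f,
                            time = snap$time %||% NA_real_), eb)
  })
  out <- bind_rows(rows)
  class(out) <- setdiff(class(out), "energy_breakdown")
  out
}

#' Hotspot residues of a snapshot interface
#'
#' Each energy term is split equally between its two residues; a residue's
#' stabilizing energy is the sum of its shares, and it is a hotspot when that
#' energy is at or below `config$hotspot_threshold`. The equal split
#' conserves energy: the per-residue energies sum to the total.
#'
#' @param snap A [snapshot()].
#' @param config [energy_config()].
#' @param chain_a,chain_b Chain identifiers.
#' @return Tibble with `node_id`, `chain`, `resno`, `resname`, `energy`,
#'   `hotspot`, sorted by energy (most stabilizing first).
#' @export
hotspots <- function(snap, config = energy_config(),
                     chain_a = "A", chain_b = "B") {
  terms <- interface_energy_terms(snap, config, chain_a, chain_b)
  if (!nrow(terms)) {
    return(tibble(node_id = character(), chain = character(),
                  resno = integer(), resname = character(),
                  energy = numeric(), hotspot = logical()))
  }
  per_res <- bind_rows(
    tibble(node_id = terms$res_i, energy = terms$energy / 2),
    tibble(node_id = terms$res_j, energy = terms$energy / 2)
  ) %>%
    group_by(.data$node_id) %>%
    summarise(energy = sum(.data$energy), .groups = "drop")
  rtab <- residues(snap)
  per_res %>%
    left_join(rtab[, c("node_id", "chain", "resno", "resname")],
              by = "node_id") %>%
    mutate(hotspot = .data$energy <= config$hotspot_threshold) %>%
    arrange(.data$energy, .data$node_id) %>%
    select("node_id", "chain", "resno", "resname", "energy", "hotspot")
}
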