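# Conformational metrics over snapshots and ensembles: least-squares
# superposition RMSD, radius of gyration, and per-residue RMSF over a
# trailing window.

# logical atom mask for a selection keyword
selection_mask <- function(atoms, selection = c("backbone", "calpha", "heavy", "all")) {
  if (is.logical(selection)) return(selection)
  selection <- match.arg(selection)
  switch(selection,
    backbone = atoms$is_backbone,
    calpha = atoms$atom_name == "CA",
    heavy = atoms$element != "H",
    all = rep(TRUE, nrow(atoms))
  )
}

#' Optimal least-squares superposition (Kabsch) of two snapshots
#'
#' Finds the rigid rotation+translation of `mobile` that minimises the
#' squared deviation to `reference` over the selected atoms, and reports the
#' RMSD over that selection after superposition.
#'
#' @param mobile,reference [snapshot()]s with identical topology.
#' @param selection `"backbone"` (N, CA, C, O; default), `"calpha"`,
#'   `"heavy"`, `"all"`, or a logical atom mask.
#' @return List with `snapshot` (transformed mobile) and `rmsd` (A).
#' @export
kabsch_superpose <- function(mobile, reference, selection = "backbone") {
  stopifnot(inherits(mobile, "snapshot"), inherits(reference, "snapshot"))
  if (nrow(mobile$atoms) != nrow(reference$atoms)) {
    stop_interlock("snapshots differ in atom count", "interlock_topology_error")
  }
  mask <- selection_mask(mobile$atoms, selection)
  if (!any(mask)) {
    stop_interlock("empty atom selection", "interlock_spec_error")
  }
  fitted <- superpose_xyz(mobile$xyz, reference$xyz, mask)
  dev <- fitted[mask, , drop = FALSE] - reference$xyz[mask, , drop = FALSE]
  list(
    snapshot = snapshot(mobile$atoms, fitted, mobile$model_index, mobile$time),
    rmsd = sqrt(mean(rowSums(dev^2)))
  )
}

# fit an n x 3 coordinate matrix onto a reference over masked atoms
superpose_xyz <- function(mobile, reference, mask) {
  mvec <- as.vector(t(mobile))
  rvec <- as.vector(t(reference))
  fitmask <- rep(mask, each = 3)
  fitted <- bio3d::rot.lsq(mvec, rvec, xfit = fitmask)
  matrix(fitted, ncol = 3, byrow = TRUE)
}

#' Per-frame RMSD of an ensemble against a reference
#'
#' Each frame is superposed onto the reference over the selection before the
#' deviation is measured.
#'
#' @param ens An [ensemble()].
#' @param reference Reference [snapshot()]; default the first frame.
#' @param selection Atom selection (see [kabsch_superpose()]).
#' @return Tibble with `frame`, `time`, `rmsd` (A).
#' @export
rmsd_series <- function(ens, reference = NULL, selection = "backbone") {
  stopifnot(inherits(ens, "ensemble"))
  reference <- reference %||% get_snapshot(ens, 1)
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    kabsch_superpose(get_snapshot(ens, f), reference, selection)$rmsd
  }, numeric(1))
  tibble(
    frame = seq_along(vals),
    time = if (!is.null(ens$frame_spacing))
      (seq_along(vals) - 1) * ens$frame_spacing else NA_real_,
    rmsd = vals
  )
}

#' Radius of gyration of a snapshot
#'
#' `Rg = sqrt(sum m_k |r_k - r_com|^2 / sum m_k)`; with
#' `mass_weighted = FALSE` all masses are 1.
#'
#' @param snap A [snapshot()].
#' @param mass_weighted Weight atoms by mass (default TRUE).
#' @return Rg in A.
#' @export
radius_of_gyration <- function(snap, mass_weighted = TRUE) {
  stopifnot(inherits(snap, "snapshot"))
  m <- if (mass_weighted) snap$atoms$mass else rep(1, nrow(snap$atoms))
  com <- colSums(snap$xyz * m) / sum(m)
  dev2 <- rowSums(sweep(snap$xyz, 2, com)^2)
  sqrt(sum(m * dev2) / sum(m))
}

#' Radius-of-gyration series over an ensemble
#'
#' @param ens An [ensemble()].
#' @param mass_weighted Weight atoms by mass (default TRUE).
#' @return Tibble with `frame`, `time`, `rg` (A).
#' @export
rg_series <- function(ens, mass_weighted = TRUE) {
  stopifnot(inherits(ens, "ensemble"))
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    radius_of_gyration(get_snapshot(ens, f), mass_weighted)
  }, numeric(1))
  tibble(
    frame = seq_along(vals),
    time = if (!is.null(ens$frame_spacing))
      (seq_along(vals) - 1) * ens$frame_spacing else NA_real_,
    rg = vals
  )
}

#' Per-residue RMSF over a trailing window
#'
#' C-alpha root-mean-square fluctuation about the window-mean structure:
#' every window frame is superposed onto the running mean (two iterations of
#' mean-structure refinement), then `RMSF = sqrt(mean |r - rbar|^2)` per
#' residue.
#'
#' @param ens An [ensemble()].
#' @param window Trailing fraction of frames in `(0, 1]` (default 0.2), or an
#'   integer vector of frame indices.
#' @return Tibble with `node_id`, `chain`, `resno`, `resname`, `rmsf` (A).
#' @export
rmsf <- function(ens, window = 0.2) {
  stopifnot(inherits(ens, "ensemble"))
  nfr <- n_frames(ens)
  frames <- if (length(window) == 1 && window > 0 && window <= 1) {
    seq(max(1, nfr - ceiling(window * nfr) + 1), nfr)
  } else {
    as.integer(window)
  }
  if (length(frames) < 2) {
    stop_interlock("RMSF window must contain at least 2 frames",
                   "interlock_spec_error")
  }
  mask <- selection_mask(ens$atoms, "calpha")
  if (!any(mask)) stop_interlock("no C-alpha atoms", "interlock_spec_error")
  coords <- lapply(frames, function(f) ens$xyz[[f]])
  mean_xyz <- coords[[1]]
  for (iter in 1:2) {
    coords <- lapply(coords, superpose_xyz, reference = mean_xyz, mask = mask)
    mean_xyz <- Reduce(`+`, coords) / length(coords)
  }
  ca <- which(mask)
  dev2 <- sapply(coords, function(m) {
    rowSums((m[ca, , drop = FALSE] - mean_xyz[ca, , drop = FALSE])^2)
  })
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = 1)
  vals <- sqrt(rowMeans(dev2))
  at <- ens$atoms
  tibble(
    node_id = at$node_id[ca], chain = at$chain[ca], resno = at$resno[ca],
    resname = at$resname[ca], rmsf = vals
  )
}
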