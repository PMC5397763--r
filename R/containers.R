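# Core data containers: msa, snapshot, ensemble.
#
# A snapshot holds a topology tibble (one row per atom) plus an n_atoms x 3
# coordinate matrix in Angstrom. An ensemble shares one topology across an
# ordered list of coordinate matrices, which keeps the topology-invariance
# guarantee structural rather than something to re-check per frame.

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths, residues
#'   upper-cased; gap is `-`).
#' @return An object of class `msa`: list with `ids`, `seqs`, `n_cols`.
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop_interlock("`ids` and `seqs` must have the same length", "interlock_id_error")
  }
  if (anyDuplicated(ids)) {
    stop_interlock("duplicate sequence identifiers in alignment", "interlock_id_error")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    stop_interlock(
      sprintf("alignment rows have unequal lengths (%s)",
              paste(sort(unique(widths)), collapse = ", ")),
      "interlock_alignment_length_error"
    )
  }
  structure(
    list(ids = ids, seqs = seqs, n_cols = if (length(widths)) widths[[1]] else 0L),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(), 0, x$n_cols)
  rownames(m) <- x$ids
  m
}

#' @export
as_tibble.msa <- function(x, ...) {
  tibble(id = x$ids, sequence = x$seqs)
}

# integer-encode an msa: 1..20 per aa_alphabet(), NA for gap/'X'/other
encode_msa <- function(msa) {
  m <- as.matrix(msa)
  code <- match(m, aa_alphabet())
  matrix(code, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
}

# gap indicator (gap '-', '.', or unknown 'X' all count as gap)
msa_gaps <- function(msa) {
  m <- as.matrix(msa)
  matrix(m %in% c("-", ".", "X"), nrow = nrow(m), ncol = ncol(m))
}

# ---- coordinate containers --------------------------------------------------

new_atoms_tibble <- function(chain, resno, insert, resname, atom_name,
                             element = NULL) {
  element <- element %||% element_from_name(atom_name)
  element[element == "" | is.na(element)] <-
    element_from_name(atom_name[element == "" | is.na(element)])
  mass <- unname(element_masses[element])
  if (anyNA(mass)) {
    bad <- unique(element[is.na(mass)])
    stop_interlock(sprintf("unknown element(s): %s", paste(bad, collapse = ", ")),
                   "interlock_parse_error")
  }
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  key <- paste(chain, resno, insert, sep = "\r")
  res_index <- match(key, unique(key))
  tibble(
    chain = as.character(chain),
    resno = as.integer(resno),
    insert = as.character(insert),
    resname = as.character(resname),
    res_index = res_index,
    atom_name = as.character(atom_name),
    element = element,
    mass = mass,
    is_backbone = atom_name %in% backbone_names,
    node_id = residue_id(chain, resno, insert)
  )
}

#' Construct a single coordinate snapshot
#'
#' @param atoms Atom topology tibble (see [read_pdb()]); one row per atom.
#' @param xyz Numeric matrix `n_atoms x 3`, Angstrom.
#' @param model_index Integer model number (>= 1).
#' @param time Optional time stamp in picoseconds.
#' @return Object of class `snapshot`.
#' @export
snapshot <- function(atoms, xyz, model_index = 1L, time = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == nrow(atoms))
  if (!all(is.finite(xyz))) {
    stop_interlock("non-finite coordinates in snapshot", "interlock_parse_error")
  }
  structure(
    list(atoms = atoms, xyz = xyz, model_index = as.integer(model_index),
         time = time),
    class = "snapshot"
  )
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> model %d: %d atoms, %d residues, chains %s\n",
              x$model_index, nrow(x$atoms), max(x$atoms$res_index),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Construct a coordinate ensemble
#'
#' @param atoms Shared atom topology tibble.
#' @param xyz_list List of `n_atoms x 3` coordinate matrices, one per frame.
#' @param frame_spacing Optional frame spacing in picoseconds.
#' @return Object of class `ensemble`.
#' @export
ensemble <- function(atoms, xyz_list, frame_spacing = NULL) {
  if (length(xyz_list) == 0) {
    stop_interlock("ensemble must contain at least one snapshot",
                   "interlock_topology_error")
  }
  for (m in xyz_list) {
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != nrow(atoms)) {
      stop_interlock("all frames must share the ensemble topology",
                     "interlock_topology_error")
    }
  }
  structure(
    list(atoms = atoms, xyz = xyz_list, frame_spacing = frame_spacing),
    class = "ensemble"
  )
}

#' Number of frames in an ensemble
#' @param x An `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  length(x$xyz)
}

#' Extract one frame of an ensemble as a snapshot
#' @param x An `ensemble`.
#' @param i Frame index (1-based).
#' @return A `snapshot`.
#' @export
get_snapshot <- function(x, i) {
  stopifnot(inherits(x, "ensemble"))
  if (i < 1 || i > length(x$xyz)) {
    stop_interlock(sprintf("frame %d out of range 1..%d", i, length(x$xyz)),
                   "interlock_lookup_error")
  }
  tm <- if (!is.null(x$frame_spacing)) (i - 1) * x$frame_spacing else NULL
  snapshot(x$atoms, x$xyz[[i]], model_index = i, time = tm)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames, %d atoms, %d residues\n",
              length(x$xyz), nrow(x$atoms), max(x$atoms$res_index)))
  invisible(x)
}

#' Per-residue summary of a snapshot or ensemble topology
#'
#' @param atoms An atoms tibble, `snapshot`, or `ensemble`.
#' @return Tibble with one row per residue: `node_id`, `chain`, `resno`,
#'   `insert`, `resname`, `res_index`, `n_atoms`.
#' @export
residues <- function(atoms) {
  if (inherits(atoms, c("snapshot", "ensemble"))) atoms <- atoms$atoms
  atoms %>%
    group_by(.data$res_index) %>%
    summarise(
      node_id = .data$node_id[[1]], chain = .data$chain[[1]],
      resno = .data$resno[[1]], insert = .data$insert[[1]],
      resname = .data$resname[[1]], n_atoms = dplyr::n(),
      .groups = "drop"
    ) %>%
    select("node_id", "chain", "resno", "insert", "resname", "res_index", "n_atoms")
}

# resolve residue selectors like "A:12" to res_index values
resolve_residue <- function(atoms, id) {
  if (inherits(atoms, c("snapshot", "ensemble"))) atoms <- atoms$atoms
  idx <- atoms$res_index[match(id, atoms$node_id)]
  if (anyNA(idx)) {
    stop_interlock(sprintf("residue(s) not found: %s",
                           paste(id[is.na(idx)], collapse = ", ")),
                   "interlock_lookup_error")
  }
  idx
}
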