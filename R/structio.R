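# File I/O: multi-model PDB and aligned FASTA.
#
# Parsing is delegated to bio3d / Biostrings; this layer adds the validation
# the rest of the pipeline relies on (per-model topology consistency, altloc
# policy, aligned-row checks) and converts into the package containers.

# per-model atom signatures (name/altloc/resname/chain/resno/icode) from raw
# lines, used to reject ensembles whose models disagree in topology
pdb_model_signatures <- function(lines) {
  is_model <- startsWith(lines, "MODEL")
  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom)) {
    stop_interlock("no ATOM records found", "interlock_parse_error")
  }
  # validate coordinates of every ATOM record
  atom_idx <- which(is_atom)
  for (ln in atom_idx) {
    rec <- lines[[ln]]
    if (nchar(rec) < 54) {
      stop_interlock(sprintf("malformed ATOM record at line %d (too short)", ln),
                     "interlock_parse_error")
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(rec, 31, 38), substr(rec, 39, 46), substr(rec, 47, 54)
    )))
    if (anyNA(coords)) {
      stop_interlock(sprintf("malformed ATOM record at line %d (bad coordinates)", ln),
                     "interlock_parse_error")
    }
  }
  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of <- rep(1L, length(lines))
  model_of[model_of == 0L] <- 1L
  sig <- substr(lines[is_atom], 13, 27)
  split(sig, model_of[is_atom])
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' One snapshot is created per `MODEL` record (a single implicit model when
#' none are present). HETATM records are ignored; for alternate locations the
#' highest-occupancy conformer is kept (first on ties). All models must share
#' the same atom topology.
#'
#' @param path Path to a PDB file.
#' @param frame_spacing Optional frame spacing (ps) to attach to the ensemble.
#' @return An [ensemble()].
#' @export
read_pdb <- function(path, frame_spacing = NULL) {
  if (!file.exists(path)) {
    stop_interlock(sprintf("file not found: %s", path), "interlock_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  sigs <- pdb_model_signatures(lines)
  if (length(sigs) > 1) {
    ref <- sigs[[1]]
    for (k in seq_along(sigs)[-1]) {
      if (!identical(sigs[[k]], ref)) {
        stop_interlock(
          sprintf("model %s does not match model 1 atom topology", names(sigs)[k]),
          "interlock_topology_error"
        )
      }
    }
  }
  multi <- length(sigs) > 1
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)

  keep <- which(at$type == "ATOM")
  # altloc policy: within (chain, resno, insert, atom name) keep the
  # highest-occupancy record, first on ties
  if (length(keep)) {
    sub <- at[keep, , drop = FALSE]
    alt <- sub$alt
    has_alt <- !is.na(alt) & alt != "" & alt != " "
    if (any(has_alt)) {
      key <- paste(sub$chain, sub$resno, sub$insert, sub$elety, sep = "\r")
      occ <- ifelse(is.na(sub$o), 1, sub$o)
      ord <- order(key, -occ, seq_along(key))
      dup <- duplicated(key[ord])
      keep <- sort(keep[ord][!dup])
    }
  }
  if (!length(keep)) {
    stop_interlock("no protein ATOM records after filtering", "interlock_parse_error")
  }
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- xyz[, cols, drop = FALSE]

  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  elesy <- ifelse(is.na(elesy) | trimws(elesy) == "",
                  element_from_name(at$elety), trimws(elesy))
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- new_atoms_tibble(
    chain = chain, resno = at$resno, insert = at$insert,
    resname = at$resid, atom_name = at$elety, element = toupper(elesy)
  )
  xyz_list <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  ensemble(atoms, xyz_list, frame_spacing = frame_spacing)
}

#' Write an ensemble (or snapshot) as a PDB file
#'
#' Ensembles with more than one frame are written with MODEL/ENDMDL framing.
#' Coordinates are written at standard PDB precision (3 decimals).
#'
#' @param x An [ensemble()] or [snapshot()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "snapshot")) x <- ensemble(x$atoms, list(x$xyz))
  stopifnot(inherits(x, "ensemble"))
  if (length(x$xyz) == 0) {
    stop_interlock("cannot write an empty ensemble", "interlock_topology_error")
  }
  at <- x$atoms
  xyz <- do.call(rbind, lapply(x$xyz, function(m) as.vector(t(m))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = at$resno, resid = at$resname, chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    elety = at$atom_name, elesy = at$element,
    o = rep(1, nrow(at)), b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file. All records must have equal
#'   length; identifiers (first whitespace-delimited token of the header) must
#'   be unique. Sequences are upper-cased.
#' @return An [msa()].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) {
    stop_interlock(sprintf("file not found: %s", path), "interlock_parse_error")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  msa(ids, as.character(set))
}

#' Write an alignment as aligned FASTA
#'
#' @param x An [msa()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::BStringSet(setNames(x$seqs, x$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
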