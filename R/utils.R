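# Shared chemical tables and small helpers.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes in the canonical order used throughout the package.
#' The gap character is `-`; `X` (unknown) is treated as a gap wherever
#' residues are counted.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter map (used by reports)
aa_three_to_one <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

# atomic masses (u) for elements we expect in protein heavy/H atoms
element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)

# Derive element symbol from a PDB atom name when the element column is blank:
# strip leading digits/primes, take the first alphabetic character.
element_from_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  toupper(substr(nm, 1, 1))
}

backbone_names <- c("N", "CA", "C", "O")

#' Per-residue-type normalization constants for interaction strength
#'
#' Normalization values used in the percentage interaction strength
#' I = 100 * n_ij / sqrt(N_i * N_j) of residue interaction networks.
#' Defaults follow the values commonly used for side-chain contact
#' normalization in protein structure network studies; the table is a plain
#' named vector and fully editable via [network_params()].
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
psn_normalization <- function() {
  c(ALA = 55.76, ARG = 93.79, ASN = 73.41, ASP = 75.15, CYS = 54.95,
    GLN = 78.13, GLU = 78.83, GLY = 47.31, HIS = 83.74, ILE = 67.97,
    LEU = 72.25, LYS = 69.61, MET = 69.26, PHE = 93.31, PRO = 51.33,
    SER = 61.39, THR = 63.71, TRP = 106.70, TYR = 100.72, VAL = 62.37)
}

# Hydrogen-bond donor/acceptor roles of N/O heavy atoms, by residue type.
# Returns "donor", "acceptor", "both" or NA for atoms with no standard role.
hbond_role <- function(resname, atom_name) {
  # backbone
  if (atom_name == "N") return(if (resname == "PRO") NA_character_ else "donor")
  if (atom_name == "O" || atom_name == "OXT") return("acceptor")
  key <- paste(resname, atom_name)
  roles <- c(
    "SER OG" = "both",  "THR OG1" = "both", "TYR OH" = "both",
    "ASN OD1" = "acceptor", "ASN ND2" = "donor",
    "GLN OE1" = "acceptor", "GLN NE2" = "donor",
    "ASP OD1" = "acceptor", "ASP OD2" = "acceptor",
    "GLU OE1" = "acceptor", "GLU OE2" = "acceptor",
    "LYS NZ" = "donor",
    "ARG NE" = "donor", "ARG NH1" = "donor", "ARG NH2" = "donor",
    "HIS ND1" = "both", "HIS NE2" = "both",
    "TRP NE1" = "donor"
  )
  unname(roles[key])
}

# Formal-charge-bearing atoms: Asp/Glu carboxylate O (-1), Lys/Arg terminal N
# (+1); His neutral. Returns +1, -1 or 0.
formal_charge <- function(resname, atom_name) {
  key <- paste(resname, atom_name)
  neg <- c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2")
  pos <- c("LYS NZ", "ARG NE", "ARG NH1", "ARG NH2")
  if (key %in% neg) return(-1L)
  if (key %in% pos) return(1L)
  0L
}

# canonical residue identifier: chain:resno[insert]
residue_id <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_interlock <- function(msg, class) {
  abort(msg, class = c(class, "interlock_error"))
}
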