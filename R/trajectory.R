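#' Molecule-kind inference map
#'
#' Default mapping from residue name to molecule kind, covering the species
#' present in protein-rG4 condensate simulations: standard amino acids
#' (protein), ribonucleotides (rna), PEG crowders, K+/Cl- ions and water.
#'
#' @return Named character vector; names are residue names, values one of
#'   `"protein"`, `"rna"`, `"crowder"`, `"ion"`, `"solvent"`.
#' @export
default_kind_map <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  nt <- c("A", "U", "G", "C", "RA", "RU", "RG", "RC")
  c(stats::setNames(rep("protein", length(aa)), aa),
    stats::setNames(rep("rna", length(nt)), nt),
    PEG = "crowder",
    K = "ion", CL = "ion",
    HOH = "solvent", SOL = "solvent", TIP3 = "solvent")
}

MOLECULE_KINDS <- c("protein", "rna", "crowder", "ion", "solvent")

#' Assign molecule kinds from residue names
#'
#' @param atoms Atom data frame (see [frame()]).
#' @param kind_map Named character vector mapping residue names to kinds;
#'   see [default_kind_map()].
#' @return `atoms` with the `molecule_kind` column filled.
#' @export
assign_molecule_kind <- function(atoms, kind_map = default_kind_map()) {
  kinds <- unname(kind_map[atoms$residue_name])
  missing <- is.na(kinds)
  if (any(missing)) {
    stop("no molecule kind mapping for residue name(s): ",
         paste(unique(atoms$residue_name[missing]), collapse = ", "))
  }
  atoms$molecule_kind <- kinds
  atoms
}

#' Construct a coordinate frame
#'
#' A frame is the basic coordinate container of the package: a data frame of
#' atom records with 3-D positions in Angstrom, optionally a periodic box and
#' a time stamp. All geometric analyses (hydrogen bonds, contacts, density
#' profiles) operate on frames.
#'
#' @param atoms Data frame with columns `atom_id` (integer, unique),
#'   `atom_name`, `element`, `residue_name`, `residue_id` (integer),
#'   `molecule_id` (integer), `molecule_kind` (one of protein, rna, crowder,
#'   ion, solvent), and coordinates `x`, `y`, `z` in Angstrom.
#' @param box Optional numeric length-3 box vector (Angstrom).
#' @param time Time stamp of the frame (unit declared by the caller; the
#'   synthetic generators use seconds).
#' @return Object of class `g4_frame`.
#' @export
frame <- function(atoms, box = NULL, time = 0) {
  required <- c("atom_id", "atom_name", "element", "residue_name",
                "residue_id", "molecule_id", "molecule_kind", "x", "y", "z")
  miss <- setdiff(required, names(atoms))
  if (length(miss) > 0) {
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(atoms$atom_id)) stop("atom_ids must be unique")
  if (any(!nzchar(atoms$atom_name))) stop("atom_name must be non-empty")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("positions must be finite")
  bad <- !atoms$molecule_kind %in% MOLECULE_KINDS
  if (any(bad)) {
    stop("unknown molecule_kind: ",
         paste(unique(atoms$molecule_kind[bad]), collapse = ", "))
  }
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 box = box, time = time),
            class = "g4_frame")
}

#' @export
print.g4_frame <- function(x, ...) {
  cat(sprintf("<g4_frame> %d atoms, %d molecule(s), t = %g\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)), x$time))
  invisible(x)
}

#' Construct a trajectory
#'
#' An ordered sequence of frames with a uniform time step. Every frame must
#' carry the same atoms in the same order; analyses rely on this stable
#' ordering.
#'
#' @param frames List of [frame()] objects.
#' @param dt Time between successive frames (> 0), in the caller's time unit.
#' @return Object of class `g4_trajectory`.
#' @export
trajectory <- function(frames, dt = 1) {
  if (length(frames) < 1) stop("trajectory must contain at least one frame")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  ref <- frames[[1]]$atoms$atom_id
  for (i in seq_along(frames)) {
    ids <- frames[[i]]$atoms$atom_id
    if (length(ids) != length(ref) || any(ids != ref)) {
      stop("frame ", i, " does not match frame 1 in atom count or ordering")
    }
  }
  structure(list(frames = frames, dt = dt), class = "g4_trajectory")
}

#' @export
print.g4_trajectory <- function(x, ...) {
  cat(sprintf("<g4_trajectory> %d frames x %d atoms, dt = %g\n",
              length(x$frames), nrow(x$frames[[1]]$atoms), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `g4_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Select atoms from a frame
#'
#' Returns the atoms matching the conjunction of the provided filters, in
#' their original order. An empty selection is a valid result.
#'
#' @param frm A `g4_frame`.
#' @param by_kind Optional molecule kind (e.g. `"protein"`).
#' @param by_residue_name Optional residue name (e.g. `"G"`).
#' @param by_atom_name Optional character vector of atom names.
#' @param by_molecule_id Optional molecule id(s).
#' @return Data frame of atom records (possibly zero rows).
#' @export
select_atoms <- function(frm, by_kind = NULL, by_residue_name = NULL,
                         by_atom_name = NULL, by_molecule_id = NULL) {
  a <- frm$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(by_kind)) keep <- keep & a$molecule_kind %in% by_kind
  if (!is.null(by_residue_name)) keep <- keep & a$residue_name %in% by_residue_name
  if (!is.null(by_atom_name)) keep <- keep & a$atom_name %in% by_atom_name
  if (!is.null(by_molecule_id)) keep <- keep & a$molecule_id %in% by_molecule_id
  a[keep, , drop = FALSE]
}

# coordinate matrix of an atom table
atom_xyz <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# heavy atoms = element other than hydrogen
heavy_only <- function(atoms) atoms[atoms$element != "H", , drop = FALSE]
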