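#' Hydrogen-bond detection criteria
#'
#' Geometric criteria for hydrogen-bond detection: donor-acceptor distance
#' cutoff and the deviation of the donor-hydrogen-acceptor angle from
#' linearity (so `angle_dev_max = 30` accepts D-H-A angles >= 150 degrees,
#' VMD-style). Defaults target guanine Hoogsteen donations: donors N1, N2;
#' acceptors N7, O6; 3.5 A; 30 degrees. The ribose 2'-hydroxyl (O2') can be
#' added to `donor_atoms` to widen the donor set.
#'
#' @param donor_atoms Atom names acting as donors.
#' @param acceptor_atoms Atom names acting as acceptors.
#' @param d_max Donor-acceptor distance cutoff, Angstrom (inclusive).
#' @param angle_dev_max Max deviation of D-H-A from 180 degrees.
#' @param require_hydrogens If TRUE (default), a bond requires a hydrogen
#'   covalently attached to the donor satisfying the angle criterion; donors
#'   with no attached hydrogen are skipped with a warning. If FALSE,
#'   detection is distance-only.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(donor_atoms = c("N1", "N2"),
                           acceptor_atoms = c("N7", "O6"),
                           d_max = 3.5, angle_dev_max = 30,
                           require_hydrogens = TRUE) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (angle_dev_max <= 0 || angle_dev_max > 90) {
    stop("angle_dev_max must be in (0, 90]")
  }
  structure(list(donor_atoms = donor_atoms, acceptor_atoms = acceptor_atoms,
                 d_max = d_max, angle_dev_max = angle_dev_max,
                 require_hydrogens = require_hydrogens),
            class = "hbond_criteria")
}

# covalent X-H search radius (A)
.H_BOND_LEN_MAX <- 1.25

# hydrogens attached to a donor atom: same residue, within covalent range
.attached_hydrogens <- function(atoms, donor_row) {
  h <- atoms[atoms$element == "H" &
               atoms$molecule_id == donor_row$molecule_id &
               atoms$residue_id == donor_row$residue_id, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  d <- sqrt((h$x - donor_row$x)^2 + (h$y - donor_row$y)^2 +
              (h$z - donor_row$z)^2)
  h[d <= .H_BOND_LEN_MAX, , drop = FALSE]
}

#' Detect hydrogen bonds in a frame
#'
#' Finds all donor-acceptor pairs (donor and acceptor in different residues)
#' with distance <= `d_max`, and - when hydrogens are required - at least one
#' donor-attached hydrogen whose D-H-A angle deviates from linearity by at
#' most `angle_dev_max` degrees. Output is ordered by (donor atom id,
#' acceptor atom id). Distance comparison is inclusive at the cutoff.
#'
#' @param frm A [frame()].
#' @param criteria An [hbond_criteria()].
#' @param donors Optional atom table restricting the donor search (default:
#'   all atoms named in `criteria$donor_atoms`).
#' @param acceptors Optional atom table restricting acceptors (default: all
#'   atoms named in `criteria$acceptor_atoms`).
#' @return Data frame with one row per bond: `donor_id`, `hydrogen_id`
#'   (NA when distance-only), `acceptor_id`, donor/acceptor molecule and
#'   residue identifiers, `distance` (A) and `angle_dev` (degrees, NA when
#'   distance-only).
#' @export
find_hbonds <- function(frm, criteria = hbond_criteria(),
                        donors = NULL, acceptors = NULL) {
  a <- frm$atoms
  if (is.null(donors)) {
    donors <- a[a$atom_name %in% criteria$donor_atoms, , drop = FALSE]
  }
  if (is.null(acceptors)) {
    acceptors <- a[a$atom_name %in% criteria$acceptor_atoms, , drop = FALSE]
  }
  empty <- data.frame(donor_id = integer(), hydrogen_id = integer(),
                      acceptor_id = integer(),
                      donor_molecule = integer(), donor_residue = integer(),
                      acceptor_molecule = integer(),
                      acceptor_residue = integer(),
                      distance = numeric(), angle_dev = numeric())
  if (nrow(donors) == 0 || nrow(acceptors) == 0) return(empty)

  acc_xyz <- atom_xyz(acceptors)
  out <- vector("list", nrow(donors))
  skipped <- 0L
  for (i in seq_len(nrow(donors))) {
    don <- donors[i, ]
    hyd <- NULL
    if (criteria$require_hydrogens) {
      hyd <- .attached_hydrogens(a, don)
      if (nrow(hyd) == 0) { skipped <- skipped + 1L; next }
    }
    dvec <- c(don$x, don$y, don$z)
    dd <- sqrt(colSums((t(acc_xyz) - dvec)^2))
    ok <- dd <= criteria$d_max &
      !(acceptors$molecule_id == don$molecule_id &
          acceptors$residue_id == don$residue_id)
    if (!any(ok)) next
    cand <- which(ok)
    keep <- logical(length(cand))
    best_h <- rep(NA_integer_, length(cand))
    best_dev <- rep(NA_real_, length(cand))
    if (criteria$require_hydrogens) {
      for (j in seq_along(cand)) {
        avec <- acc_xyz[cand[j], ]
        for (k in seq_len(nrow(hyd))) {
          hvec <- c(hyd$x[k], hyd$y[k], hyd$z[k])
          v1 <- dvec - hvec
          v2 <- avec - hvec
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          cosang <- max(-1, min(1, cosang))
          dev <- 180 - acos(cosang) * 180 / pi
          if (dev <= criteria$angle_dev_max &&
              (is.na(best_dev[j]) || dev < best_dev[j])) {
            keep[j] <- TRUE
            best_h[j] <- hyd$atom_id[k]
            best_dev[j] <- dev
          }
        }
      }
    } else {
      keep[] <- TRUE
    }
    if (!any(keep)) next
    cand <- cand[keep]
    out[[i]] <- data.frame(
      donor_id = don$atom_id, hydrogen_id = best_h[keep],
      acceptor_id = acceptors$atom_id[cand],
      donor_molecule = don$molecule_id, donor_residue = don$residue_id,
      acceptor_molecule = acceptors$molecule_id[cand],
      acceptor_residue = acceptors$residue_id[cand],
      distance = dd[cand], angle_dev = best_dev[keep])
  }
  if (skipped > 0) {
    warning(skipped, " donor(s) skipped: no covalently attached hydrogen")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res <- res[order(res$donor_id, res$acceptor_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# residue names recognized as guanine
.GUANINE_NAMES <- c("G", "RG", "GUA")

#' Count Hoogsteen hydrogen bonds over a trajectory
#'
#' Counts guanine-to-guanine hydrogen bonds (donors N1/N2, acceptors N7/O6
#' by default) per frame, the standard readout of G-quadruplex structural
#' integrity: an intact quartet contributes 8 bonds, a five-quartet
#' quadruplex 40.
#'
#' @param traj A [trajectory()].
#' @param criteria An [hbond_criteria()].
#' @param per_molecule If TRUE, additionally split counts by the donor's
#'   molecule id (splits sum to the total).
#' @return Data frame `frame` (1-based), `time`, `count`; with
#'   `per_molecule`, columns `frame`, `time`, `molecule_id`, `count`.
#' @export
count_hoogsteen <- function(traj, criteria = hbond_criteria(),
                            per_molecule = FALSE) {
  res <- lapply(seq_along(traj$frames), function(i) {
    frm <- traj$frames[[i]]
    gua <- frm$atoms[frm$atoms$residue_name %in% .GUANINE_NAMES, , drop = FALSE]
    donors <- gua[gua$atom_name %in% criteria$donor_atoms, , drop = FALSE]
    acceptors <- gua[gua$atom_name %in% criteria$acceptor_atoms, , drop = FALSE]
    hb <- find_hbonds(frm, criteria, donors, acceptors)
    if (per_molecule) {
      mols <- sort(unique(gua$molecule_id))
      cnt <- vapply(mols, function(m) sum(hb$donor_molecule == m), integer(1))
      data.frame(frame = i, time = frm$time, molecule_id = mols, count = cnt)
    } else {
      data.frame(frame = i, time = frm$time, count = nrow(hb))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
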