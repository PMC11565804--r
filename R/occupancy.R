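#' Hydrogen-bond occupancy over a trajectory
#'
#' For every donor-residue/acceptor-residue pair observed to hydrogen bond,
#' the occupancy is the fraction of frames in which at least one bond exists
#' between the pair. Typical use: protein side donating to the RNA side to
#' rank the residue pairs that anchor a protein-RNA interface.
#'
#' @param traj A [trajectory()].
#' @param criteria An [hbond_criteria()] (supply donor/acceptor atom names
#'   appropriate for the donor and acceptor species).
#' @param donor_kind Molecule kind of the donor side (default `"protein"`).
#' @param acceptor_kind Molecule kind of the acceptor side (default `"rna"`).
#' @return Data frame sorted by descending occupancy with columns
#'   `donor_molecule`, `donor_residue`, `acceptor_molecule`,
#'   `acceptor_residue`, `occupancy` (in \[0, 1\]) and `n_frames`.
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            donor_kind = "protein", acceptor_kind = "rna") {
  nf <- length(traj$frames)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    frm <- traj$frames[[i]]
    a <- frm$atoms
    donors <- a[a$molecule_kind %in% donor_kind &
                  a$atom_name %in% criteria$donor_atoms, , drop = FALSE]
    acceptors <- a[a$molecule_kind %in% acceptor_kind &
                     a$atom_name %in% criteria$acceptor_atoms, , drop = FALSE]
    hb <- find_hbonds(frm, criteria, donors, acceptors)
    if (nrow(hb) == 0) next
    keys <- unique(paste(hb$donor_molecule, hb$donor_residue,
                         hb$acceptor_molecule, hb$acceptor_residue, sep = "/"))
    for (k in keys) {
      seen[[k]] <- c(if (is.null(seen[[k]])) integer() else seen[[k]], i)
    }
  }
  keys <- ls(seen)
  if (length(keys) == 0) {
    return(data.frame(donor_molecule = integer(), donor_residue = integer(),
                      acceptor_molecule = integer(),
                      acceptor_residue = integer(),
                      occupancy = numeric(), n_frames = integer()))
  }
  parts <- do.call(rbind, strsplit(keys, "/", fixed = TRUE))
  out <- data.frame(donor_molecule = as.integer(parts[, 1]),
                    donor_residue = as.integer(parts[, 2]),
                    acceptor_molecule = as.integer(parts[, 3]),
                    acceptor_residue = as.integer(parts[, 4]),
                    occupancy = vapply(keys, function(k)
                      length(seen[[k]]) / nf, numeric(1)),
                    n_frames = nf)
  out <- out[order(-out$occupancy, out$donor_molecule, out$donor_residue,
                   out$acceptor_molecule, out$acceptor_residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
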