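#' Optimal-superposition RMSD between two coordinate sets
#'
#' Least-squares (Kabsch) superposition: both sets are centered, the optimal
#' rotation is found by SVD (with proper-rotation correction), and the RMSD
#' of the superposed coordinates is returned. Symmetric in its arguments.
#'
#' @param A,B n x 3 coordinate matrices with matching row order.
#' @return RMSD in the coordinate unit.
#' @export
kabsch_rmsd <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("coordinate sets must match in size")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(t(B) %*% A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(sum((A - B %*% t(R))^2) / nrow(A))
}

# default clustering selection: backbone heavy atoms of one molecule
.cluster_selection <- function(frm, molecule_id = NULL, atom_names = NULL) {
  a <- frm$atoms
  if (is.null(molecule_id)) molecule_id <- min(a$molecule_id)
  if (is.null(atom_names)) atom_names <- c("N", "CA", "C", "O", "P", "C1'")
  sel <- which(a$molecule_id == molecule_id & a$atom_name %in% atom_names)
  if (length(sel) == 0) {
    # bead models may not use backbone names; fall back to all heavy atoms
    sel <- which(a$molecule_id == molecule_id & a$element != "H")
  }
  sel
}

#' GROMOS (Daura) conformational clustering
#'
#' Clusters trajectory frames by pairwise optimal-superposition RMSD using
#' the Daura algorithm: repeatedly take the frame with the most neighbors
#' within `rmsd_cutoff` as a cluster center, assign it and its neighbors to
#' that cluster, remove them and iterate. The first center is the
#' representative conformation of maximum population. Ties in neighbor
#' count are broken by the lowest frame index.
#'
#' @param traj A [trajectory()] (coordinates in Angstrom).
#' @param rmsd_cutoff Cutoff in nanometers (default 0.2 nm = 2 A).
#' @param molecule_id Molecule whose conformation is clustered (default the
#'   lowest molecule id).
#' @param atom_names Atom-name selection (default backbone heavy atoms
#'   N, CA, C, O, P, C1'; falls back to all heavy atoms of the molecule for
#'   bead models).
#' @return List of class `cluster_result`: `assignments` (integer vector,
#'   frame -> cluster id, 1-based), `centers` (cluster id -> frame index),
#'   `sizes`, `rmsd_cutoff` (nm).
#' @export
cluster_conformations <- function(traj, rmsd_cutoff = 0.2,
                                  molecule_id = NULL, atom_names = NULL) {
  nf <- length(traj$frames)
  sel <- .cluster_selection(traj$frames[[1]], molecule_id, atom_names)
  if (length(sel) == 0) stop("empty atom selection for clustering")
  cutoff_A <- rmsd_cutoff * 10  # nm -> Angstrom

  coords <- lapply(traj$frames, function(f) atom_xyz(f$atoms[sel, , drop = FALSE]))
  rmsd <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        rmsd[i, j] <- rmsd[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
      }
    }
  }
  neighbor <- rmsd <= cutoff_A

  assignments <- rep(NA_integer_, nf)
  centers <- integer()
  sizes <- integer()
  remaining <- rep(TRUE, nf)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(neighbor[remaining, , drop = FALSE]) # includes self
    counts[!remaining] <- -1L
    center <- which.max(counts)  # which.max takes the first max: lowest index
    members <- which(remaining & neighbor[center, ])
    assignments[members] <- cl
    centers[cl] <- center
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  structure(list(assignments = assignments, centers = centers,
                 sizes = sizes, rmsd_cutoff = rmsd_cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) over %d frames (cutoff %g nm)\n",
              length(x$centers), length(x$assignments), x$rmsd_cutoff))
  cat("  sizes:", paste(x$sizes, collapse = ", "),
      "| representative frame:", x$centers[1], "\n")
  invisible(x)
}
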