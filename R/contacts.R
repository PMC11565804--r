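#' Intermolecular contact criteria
#'
#' A protein and an RNA molecule are "in contact" when their minimum
#' inter-atomic distance is at or below the cutoff: 8 A for protein-RNA
#' contacts, 6 A for crowder proximity. The distance is computed over heavy
#' atoms by default.
#'
#' @param cutoff Distance cutoff, Angstrom (default 8).
#' @param atom_scope `"heavy_atoms"` (default) or `"all_atoms"`.
#' @return Object of class `contact_criteria`.
#' @export
contact_criteria <- function(cutoff = 8,
                             atom_scope = c("heavy_atoms", "all_atoms")) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, atom_scope = match.arg(atom_scope)),
            class = "contact_criteria")
}

.scope_atoms <- function(atoms, criteria) {
  if (criteria$atom_scope == "heavy_atoms") heavy_only(atoms) else atoms
}

# minimum distance between two coordinate sets
.min_dist <- function(A, B) {
  # outer squared distances without forming huge intermediates: sizes here
  # are per-molecule, small
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Protein-RNA contact graph of a frame
#'
#' Builds the bipartite contact graph between protein and RNA molecules:
#' an edge is present iff the minimum inter-molecular atom distance is
#' <= the cutoff, and the minimum distance is recorded per edge.
#'
#' @param frm A [frame()].
#' @param criteria A [contact_criteria()].
#' @return List of class `contact_graph`: `edges` data frame
#'   (`protein_id`, `rna_id`, `min_dist`), plus `protein_ids`, `rna_ids`.
#' @export
contact_graph <- function(frm, criteria = contact_criteria()) {
  a <- .scope_atoms(frm$atoms, criteria)
  prot <- a[a$molecule_kind == "protein", , drop = FALSE]
  rna <- a[a$molecule_kind == "rna", , drop = FALSE]
  p_ids <- sort(unique(prot$molecule_id))
  r_ids <- sort(unique(rna$molecule_id))
  edges <- data.frame(protein_id = integer(), rna_id = integer(),
                      min_dist = numeric())
  if (length(p_ids) == 0 || length(r_ids) == 0) {
    warning("frame has no protein or no RNA molecules; empty contact graph")
  } else {
    p_xyz <- lapply(p_ids, function(m) atom_xyz(prot[prot$molecule_id == m, ]))
    r_xyz <- lapply(r_ids, function(m) atom_xyz(rna[rna$molecule_id == m, ]))
    for (i in seq_along(p_ids)) {
      for (j in seq_along(r_ids)) {
        md <- .min_dist(p_xyz[[i]], r_xyz[[j]])
        if (md <= criteria$cutoff) {
          edges <- rbind(edges, data.frame(protein_id = p_ids[i],
                                           rna_id = r_ids[j], min_dist = md))
        }
      }
    }
  }
  structure(list(edges = edges, protein_ids = p_ids, rna_ids = r_ids),
            class = "contact_graph")
}

#' Contact partners per molecule
#'
#' Node degrees of a contact graph: the number of RNA partners of each
#' protein, or protein partners of each RNA (the multivalency readout).
#'
#' @param graph A [contact_graph()].
#' @param side `"rna"` (partners per RNA molecule) or `"protein"`.
#' @return Named integer vector of degrees (0 for isolated molecules).
#' @export
contact_partners <- function(graph, side = c("rna", "protein")) {
  side <- match.arg(side)
  ids <- if (side == "rna") graph$rna_ids else graph$protein_ids
  col <- if (side == "rna") "rna_id" else "protein_id"
  deg <- vapply(ids, function(m) sum(graph$edges[[col]] == m), integer(1))
  stats::setNames(deg, ids)
}

#' Multivalency statistics over a trajectory
#'
#' Per frame, summarizes the degree distribution of each side of the
#' bipartite protein-RNA contact graph: mean and maximum partners per
#' protein and per RNA, with full degree histograms available as an
#' attribute.
#'
#' @param traj A [trajectory()].
#' @param criteria A [contact_criteria()].
#' @return Data frame `frame`, `time`, `side`, `mean_partners`,
#'   `max_partners`; attribute `histograms` holds per-frame degree tables.
#' @export
multivalency_series <- function(traj, criteria = contact_criteria()) {
  rows <- list()
  hists <- list()
  for (i in seq_along(traj$frames)) {
    g <- suppressWarnings(contact_graph(traj$frames[[i]], criteria))
    for (side in c("protein", "rna")) {
      deg <- contact_partners(g, side)
      rows[[length(rows) + 1]] <- data.frame(
        frame = i, time = traj$frames[[i]]$time, side = side,
        mean_partners = if (length(deg)) mean(deg) else 0,
        max_partners = if (length(deg)) max(deg) else 0L)
      hists[[paste(i, side, sep = ":")]] <- table(deg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  out
}

#' Crowder proximity series
#'
#' Counts, per frame, crowder molecules having any atom within the cutoff
#' (default 6 A) of any protein or RNA atom. Each crowder molecule counts at
#' most once per frame.
#'
#' @param traj A [trajectory()].
#' @param criteria A [contact_criteria()]; default cutoff 6 A.
#' @return Data frame `frame`, `time`, `count`.
#' @export
crowder_proximity <- function(traj, criteria = contact_criteria(cutoff = 6)) {
  rows <- lapply(seq_along(traj$frames), function(i) {
    frm <- traj$frames[[i]]
    a <- .scope_atoms(frm$atoms, criteria)
    crw <- a[a$molecule_kind == "crowder", , drop = FALSE]
    target <- a[a$molecule_kind %in% c("protein", "rna"), , drop = FALSE]
    cnt <- 0L
    if (nrow(crw) > 0 && nrow(target) > 0) {
      t_xyz <- atom_xyz(target)
      for (m in unique(crw$molecule_id)) {
        c_xyz <- atom_xyz(crw[crw$molecule_id == m, , drop = FALSE])
        if (.min_dist(c_xyz, t_xyz) <= criteria$cutoff) cnt <- cnt + 1L
      }
    }
    data.frame(frame = i, time = frm$time, count = cnt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
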