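#' Detect G-quartets (tetrads) in a frame
#'
#' A G-quartet is a directed cycle of four guanines in which each guanine
#' donates at least one Hoogsteen hydrogen bond to the next. Tetrads are
#' found as length-4 directed cycles in the residue-level guanine
#' hydrogen-bond graph; each guanine is assigned to at most one tetrad
#' (cycles claimed in a deterministic order keyed by residue identity), and
#' stack levels are assigned by projecting tetrad centroids onto the
#' stacking axis (the principal axis of the centroids).
#'
#' @param frm A [frame()].
#' @param criteria An [hbond_criteria()].
#' @return List of class `g4_tetrads`; each element has `residues`
#'   (data frame of molecule_id/residue_id, in cycle order) and
#'   `stack_level` (0-based, bottom first). Empty list when no quartet.
#' @export
detect_tetrads <- function(frm, criteria = hbond_criteria()) {
  gua <- frm$atoms[frm$atoms$residue_name %in% .GUANINE_NAMES, , drop = FALSE]
  out <- structure(list(), class = "g4_tetrads")
  if (nrow(gua) == 0) return(out)
  donors <- gua[gua$atom_name %in% criteria$donor_atoms, , drop = FALSE]
  acceptors <- gua[gua$atom_name %in% criteria$acceptor_atoms, , drop = FALSE]
  hb <- find_hbonds(frm, criteria, donors, acceptors)
  if (nrow(hb) == 0) return(out)

  # residue-level directed edges, nodes keyed (molecule_id, residue_id)
  res_tab <- unique(gua[, c("molecule_id", "residue_id")])
  res_tab <- res_tab[order(res_tab$molecule_id, res_tab$residue_id), ,
                     drop = FALSE]
  key <- function(m, r) paste(m, r, sep = "/")
  nodes <- key(res_tab$molecule_id, res_tab$residue_id)
  from <- match(key(hb$donor_molecule, hb$donor_residue), nodes)
  to <- match(key(hb$acceptor_molecule, hb$acceptor_residue), nodes)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(from, to)] <- TRUE

  # enumerate directed 4-cycles, canonical start = smallest node index
  cycles <- list()
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      if (j <= i) next
      for (k in which(adj[j, ])) {
        if (k <= i || k == j) next
        for (l in which(adj[k, ])) {
          if (l <= i || l == j || l == k) next
          if (adj[l, i]) cycles[[length(cycles) + 1]] <- c(i, j, k, l)
        }
      }
    }
  }
  if (length(cycles) == 0) return(out)
  ord <- order(vapply(cycles, function(cy) sum((cy - 1) * n^(3:0)), numeric(1)))
  used <- rep(FALSE, n)
  picked <- list()
  for (cy in cycles[ord]) {
    if (any(used[cy])) next
    used[cy] <- TRUE
    picked[[length(picked) + 1]] <- cy
  }

  # stack levels from centroid projection on the principal axis
  centroids <- t(vapply(picked, function(cy) {
    rows <- gua$molecule_id %in% res_tab$molecule_id[cy] &
      paste(gua$molecule_id, gua$residue_id) %in%
        paste(res_tab$molecule_id[cy], res_tab$residue_id[cy])
    colMeans(atom_xyz(heavy_only(gua[rows, , drop = FALSE])))
  }, numeric(3)))
  if (length(picked) > 1) {
    cen <- sweep(centroids, 2, colMeans(centroids))
    axis <- svd(cen)$v[, 1]
    proj <- cen %*% axis
    # orient the stacking axis so residue indices increase with level
    # (deterministic, invariant under rigid motion and atom permutation)
    mean_res <- vapply(picked, function(cy) mean(res_tab$residue_id[cy]),
                       numeric(1))
    if (stats::cov(as.numeric(proj), mean_res) < 0) proj <- -proj
    lev <- rank(proj, ties.method = "first") - 1L
  } else {
    lev <- 0L
  }
  tets <- lapply(seq_along(picked), function(t) {
    cy <- picked[[t]]
    list(residues = data.frame(molecule_id = res_tab$molecule_id[cy],
                               residue_id = res_tab$residue_id[cy]),
         stack_level = lev[t])
  })
  tets <- tets[order(vapply(tets, function(t) t$stack_level, integer(1)))]
  structure(tets, class = "g4_tetrads")
}

#' @export
print.g4_tetrads <- function(x, ...) {
  cat(sprintf("<g4_tetrads> %d tetrad(s)\n", length(x)))
  for (t in x) {
    cat(sprintf("  level %d: %s\n", t$stack_level,
                paste(sprintf("%d:%d", t$residues$molecule_id,
                              t$residues$residue_id), collapse = " -> ")))
  }
  invisible(x)
}

#' Report stacking pattern of detected tetrads
#'
#' For each pair of adjacent stack levels, pairs each guanine with its
#' nearest (centroid distance) guanine of the same strand in the level above
#' and reports the within-strand residue-index offset. A quadruplex built
#' with an i to i+6 stacking pattern reports a constant offset of 6.
#'
#' @param tetrads Result of [detect_tetrads()].
#' @param frm The frame the tetrads were detected in.
#' @return Data frame `level_from`, `level_to`, `molecule_id`,
#'   `residue_from`, `residue_to`, `offset`. Zero rows when fewer than two
#'   levels.
#' @export
tetrad_stack_report <- function(tetrads, frm) {
  if (length(tetrads) < 1) stop("need at least one tetrad")
  empty <- data.frame(level_from = integer(), level_to = integer(),
                      molecule_id = integer(), residue_from = integer(),
                      residue_to = integer(), offset = integer())
  if (length(tetrads) < 2) return(empty)
  gua <- frm$atoms[frm$atoms$residue_name %in% .GUANINE_NAMES, , drop = FALSE]
  res_centroid <- function(m, r) {
    rows <- gua$molecule_id == m & gua$residue_id == r
    colMeans(atom_xyz(heavy_only(gua[rows, , drop = FALSE])))
  }
  levels <- vapply(tetrads, function(t) t$stack_level, integer(1))
  rows <- list()
  for (lv in sort(levels)[-length(levels)]) {
    lo <- tetrads[[which(levels == lv)]]$residues
    hi <- tetrads[[which(levels == lv + 1)]]$residues
    for (i in seq_len(nrow(lo))) {
      cand <- hi[hi$molecule_id == lo$molecule_id[i], , drop = FALSE]
      if (nrow(cand) == 0) next
      c0 <- res_centroid(lo$molecule_id[i], lo$residue_id[i])
      dd <- vapply(seq_len(nrow(cand)), function(j) {
        sum((res_centroid(cand$molecule_id[j], cand$residue_id[j]) - c0)^2)
      }, numeric(1))
      j <- which.min(dd)
      rows[[length(rows) + 1]] <- data.frame(
        level_from = lv, level_to = lv + 1L,
        molecule_id = lo$molecule_id[i],
        residue_from = lo$residue_id[i], residue_to = cand$residue_id[j],
        offset = cand$residue_id[j] - lo$residue_id[i])
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
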