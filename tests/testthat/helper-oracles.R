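# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain loops,
# no vectorization, no acceleration.

# --- hydrogen bonds: naive triple loop -------------------------------------
oracle_hbonds <- function(frm, criteria) {
  a <- frm$atoms
  donors <- a[a$atom_name %in% criteria$donor_atoms, , drop = FALSE]
  acceptors <- a[a$atom_name %in% criteria$acceptor_atoms, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(donors))) {
    d <- donors[i, ]
    hs <- a[a$element == "H" & a$molecule_id == d$molecule_id &
              a$residue_id == d$residue_id, , drop = FALSE]
    if (nrow(hs) > 0) {
      hd <- sqrt((hs$x - d$x)^2 + (hs$y - d$y)^2 + (hs$z - d$z)^2)
      hs <- hs[hd <= 1.25, , drop = FALSE]
    }
    if (criteria$require_hydrogens && nrow(hs) == 0) next
    for (j in seq_len(nrow(acceptors))) {
      ac <- acceptors[j, ]
      if (ac$molecule_id == d$molecule_id && ac$residue_id == d$residue_id) next
      dist <- sqrt((ac$x - d$x)^2 + (ac$y - d$y)^2 + (ac$z - d$z)^2)
      if (dist > criteria$d_max) next
      if (!criteria$require_hydrogens) {
        hits[[length(hits) + 1]] <- c(d$atom_id, ac$atom_id)
        next
      }
      found <- FALSE
      for (k in seq_len(nrow(hs))) {
        v1 <- c(d$x - hs$x[k], d$y - hs$y[k], d$z - hs$z[k])
        v2 <- c(ac$x - hs$x[k], ac$y - hs$y[k], ac$z - hs$z[k])
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (180 - ang <= criteria$angle_dev_max) found <- TRUE
      }
      if (found) hits[[length(hits) + 1]] <- c(d$atom_id, ac$atom_id)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(donor_id = integer(), acceptor_id = integer()))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(donor_id = m[, 1], acceptor_id = m[, 2])
  out[order(out$donor_id, out$acceptor_id), , drop = FALSE]
}

# --- contacts: naive per-pair molecule scan --------------------------------
oracle_contact_edges <- function(frm, cutoff, heavy = TRUE) {
  a <- frm$atoms
  if (heavy) a <- a[a$element != "H", , drop = FALSE]
  prot <- unique(a$molecule_id[a$molecule_kind == "protein"])
  rna <- unique(a$molecule_id[a$molecule_kind == "rna"])
  edges <- list()
  for (p in prot) {
    pa <- a[a$molecule_id == p, , drop = FALSE]
    for (r in rna) {
      ra <- a[a$molecule_id == r, , drop = FALSE]
      mind <- Inf
      for (i in seq_len(nrow(pa))) {
        for (j in seq_len(nrow(ra))) {
          dd <- sqrt((pa$x[i] - ra$x[j])^2 + (pa$y[i] - ra$y[j])^2 +
                       (pa$z[i] - ra$z[j])^2)
          if (dd < mind) mind <- dd
        }
      }
      if (mind <= cutoff) edges[[length(edges) + 1]] <- c(p, r)
    }
  }
  if (length(edges) == 0) {
    return(data.frame(protein_id = integer(), rna_id = integer()))
  }
  m <- do.call(rbind, edges)
  out <- data.frame(protein_id = m[, 1], rna_id = m[, 2])
  out[order(out$protein_id, out$rna_id), , drop = FALSE]
}

oracle_crowders_near <- function(frm, cutoff) {
  a <- frm$atoms[frm$atoms$element != "H", , drop = FALSE]
  crw <- unique(a$molecule_id[a$molecule_kind == "crowder"])
  tgt <- a[a$molecule_kind %in% c("protein", "rna"), , drop = FALSE]
  n <- 0L
  for (m in crw) {
    ca <- a[a$molecule_id == m, , drop = FALSE]
    near <- FALSE
    for (i in seq_len(nrow(ca))) {
      for (j in seq_len(nrow(tgt))) {
        dd <- sqrt((ca$x[i] - tgt$x[j])^2 + (ca$y[i] - tgt$y[j])^2 +
                     (ca$z[i] - tgt$z[j])^2)
        if (dd <= cutoff) near <- TRUE
      }
    }
    if (near) n <- n + 1L
  }
  n
}

# --- G4 pattern: exhaustive recursive decomposition enumerator -------------
oracle_match_g4 <- function(seq, spec) {
  chars <- strsplit(gsub("T", "U", toupper(seq), fixed = TRUE), "")[[1]]
  n <- length(chars)
  is_g_run <- function(from, len) {
    if (from + len - 1 > n) return(FALSE)
    all(chars[from:(from + len - 1)] == "G")
  }
  rec <- function(pos, runs_left) {
    # does a decomposition with runs_left runs exist with a run starting
    # exactly at pos?
    for (len in spec$g_run_min:spec$g_run_max) {
      if (!is_g_run(pos, len)) next
      if (runs_left == 1) return(TRUE)
      for (loop in 0:spec$loop_max) {
        nxt <- pos + len + loop
        if (nxt > n) break
        if (rec(nxt, runs_left - 1)) return(TRUE)
      }
    }
    FALSE
  }
  for (start in seq_len(n)) {
    if (chars[start] == "G" && rec(start, spec$n_runs)) return(TRUE)
  }
  FALSE
}

# --- k-mers: naive sliding-window recount ----------------------------------
oracle_kmer_counts <- function(reads, k) {
  counts <- new.env(parent = emptyenv())
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in 1:(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k2) counts[[k2]], integer(1)), keys)
}

# --- Daura clustering: independent reference -------------------------------
oracle_rmsd <- function(A, B) {
  # superposition via explicit eigendecomposition of the quaternion matrix
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- t(B) %*% A
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

oracle_daura <- function(coord_list, cutoff) {
  n <- length(coord_list)
  nb <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    nb[i, j] <- oracle_rmsd(coord_list[[i]], coord_list[[j]]) <= cutoff
  }
  assign <- rep(NA_integer_, n)
  centers <- integer()
  left <- 1:n
  cl <- 0L
  while (length(left) > 0) {
    cl <- cl + 1L
    cnt <- sapply(left, function(i) sum(nb[i, left]))
    ctr <- left[which.max(cnt)]   # first max = lowest index tie-break
    mem <- left[nb[ctr, left]]
    assign[mem] <- cl
    centers[cl] <- ctr
    left <- setdiff(left, mem)
  }
  list(assignments = assign, centers = centers)
}

# --- shared fixture helpers ------------------------------------------------

# minimal atom-table constructor for hand-built frames
make_atoms <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(element = NA, residue_name = "ALA", residue_id = 1L,
                   molecule_id = 1L, molecule_kind = "protein")
  for (nm in names(defaults)) {
    if (is.null(d[[nm]])) d[[nm]] <- defaults[[nm]]
  }
  if (all(is.na(d$element))) d$element <- substr(d$atom_name, 1, 1)
  d$atom_id <- seq_len(nrow(d))
  d[, c("atom_id", "atom_name", "element", "residue_name", "residue_id",
        "molecule_id", "molecule_kind", "x", "y", "z")]
}

# random frame with donor/hydrogen/acceptor triples for h-bond fuzzing
random_hbond_frame <- function(n_res = 12, box = 14, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_res)) {
    base <- stats::runif(3, 0, box)
    hdir <- stats::rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
    rows[[length(rows) + 1]] <- data.frame(
      atom_name = c("N1", "H1", "O6"),
      element = c("N", "H", "O"),
      residue_name = "G", residue_id = r, molecule_id = r,
      molecule_kind = "rna",
      x = c(base[1], base[1] + hdir[1], base[1] + stats::runif(1, -4, 4)),
      y = c(base[2], base[2] + hdir[2], base[2] + stats::runif(1, -4, 4)),
      z = c(base[3], base[3] + hdir[3], base[3] + stats::runif(1, -4, 4)),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d$atom_id <- seq_len(nrow(d))
  frame(d[, c("atom_id", "atom_name", "element", "residue_name", "residue_id",
              "molecule_id", "molecule_kind", "x", "y", "z")])
}

# rigid rotation of every frame in a trajectory (same rotation all frames)
rotate_frame <- function(frm, angles = c(0.3, 1.1, -0.7), shift = c(5, -3, 2)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  R <- rz %*% ry %*% rx
  xyz <- as.matrix(frm$atoms[, c("x", "y", "z")]) %*% t(R)
  frm$atoms$x <- xyz[, 1] + shift[1]
  frm$atoms$y <- xyz[, 2] + shift[2]
  frm$atoms$z <- xyz[, 3] + shift[3]
  frm
}
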