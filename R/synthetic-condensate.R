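# bead-chain coordinates: n beads along a direction, spacing in Angstrom
.bead_chain <- function(center, direction, n_beads, spacing = 3.8) {
  direction <- direction / sqrt(sum(direction^2))
  offs <- (seq_len(n_beads) - (n_beads + 1) / 2) * spacing
  sweep(outer(offs, direction), 2, center, `+`)
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# minimum distance from coordinate set A to set B
.set_min_dist <- function(A, B) .min_dist(as.matrix(A), as.matrix(B))

#' Generate synthetic condensate frames with known contact structure
#'
#' Builds a coarse bead-per-residue mixture of protein, RNA and PEG-like
#' crowder chains in which the contact network is known by construction:
#' every RNA molecule has exactly `contacts_per_rna` protein molecules at a
#' minimum inter-atom distance of `contact_distance` (<= 8 A) while all
#' other proteins are kept more than 10 A away; crowders are placed at a
#' controlled minimum distance from the protein/RNA assembly. Successive
#' frames displace every molecule rigidly by Gaussian steps of per-axis
#' variance `2 * displacement_D * dt` (converted to Angstrom).
#'
#' @param n_protein,n_rna,n_crowder Molecule counts (>= 0).
#' @param contacts_per_rna Proteins in contact with each RNA (must not
#'   exceed `n_protein`).
#' @param core_inner_radius Optional inner radius (A) of a spherical shell
#'   on which molecule centers are placed (hollow-core fixtures); NULL for
#'   a spread-out planar grid layout.
#' @param n_frames Number of frames.
#' @param displacement_D Diffusion coefficient of the rigid per-molecule
#'   random walk, um^2/s (0 freezes the system).
#' @param dt Frame spacing, s.
#' @param seed Integer seed.
#' @param contact_distance Engineered protein-RNA minimum distance for
#'   contact pairs, A (default 7).
#' @param crowder_distance Engineered crowder-to-assembly minimum distance,
#'   A (default 5).
#' @param beads_per_molecule Beads per chain (default 5; crowders 3).
#' @return A [trajectory()] (coordinates in Angstrom, `dt` in seconds).
#' @export
generate_condensate_frames <- function(n_protein, n_rna, n_crowder = 0,
                                       contacts_per_rna = 0,
                                       core_inner_radius = NULL,
                                       n_frames = 1, displacement_D = 0,
                                       dt = 0.1, seed = 1,
                                       contact_distance = 7,
                                       crowder_distance = 5,
                                       beads_per_molecule = 5) {
  if (min(n_protein, n_rna, n_crowder) < 0) stop("counts must be >= 0")
  if (contacts_per_rna * n_rna > 0 && contacts_per_rna > n_protein) {
    stop("contacts_per_rna exceeds the number of proteins")
  }
  set.seed(seed)

  # anchor positions for RNA molecules, widely separated so contact
  # assignments cannot interfere across RNAs
  n_anchor <- max(n_rna, 1)
  if (is.null(core_inner_radius)) {
    side <- ceiling(sqrt(n_anchor))
    idx <- seq_len(n_anchor) - 1
    anchors <- cbind(60 * (idx %% side), 60 * (idx %/% side), 0)
  } else {
    shell_r <- core_inner_radius + 10
    u <- seq(0, 2 * pi, length.out = n_anchor + 1)[seq_len(n_anchor)]
    anchors <- cbind(shell_r * cos(u), shell_r * sin(u),
                     stats::rnorm(n_anchor, sd = 2))
  }

  mol_coords <- list()   # per molecule: bead matrix
  mol_meta <- list()     # residue_name, kind, atom prefix
  add_mol <- function(coords, kind, resname, atom_name, element) {
    mol_coords[[length(mol_coords) + 1]] <<- coords
    mol_meta[[length(mol_meta) + 1]] <<- list(kind = kind, resname = resname,
                                              atom_name = atom_name,
                                              element = element)
  }

  rna_coords <- list()
  for (r in seq_len(n_rna)) {
    coords <- .bead_chain(anchors[r, ], .rand_unit(), beads_per_molecule)
    rna_coords[[r]] <- coords
    add_mol(coords, "rna", "G", "P", "P")
  }

  # contact proteins: placed along a random direction from the RNA, then
  # shifted so the minimum inter-atom distance is exactly contact_distance
  place_near <- function(target, dist_target, n_beads = beads_per_molecule) {
    for (try in 1:100) {
      # anchor on a random target atom so the chain starts inside the
      # cutoff (min distance ~0), then push it outward until the minimum
      # distance reaches the requested value: f(0) < target < f(hi)
      anchor <- target[sample.int(nrow(target), 1), ]
      dir <- .rand_unit()
      orient <- .rand_unit()
      at_shift <- function(s) .bead_chain(anchor + dir * s, orient, n_beads)
      f <- function(s) .set_min_dist(at_shift(s), target)
      lo <- 0; hi <- 30
      while (f(hi) < dist_target && hi < 2000) hi <- hi * 2
      if (f(hi) < dist_target) next
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (f(mid) < dist_target) lo <- mid else hi <- mid
      }
      coords <- at_shift(hi)
      d <- .set_min_dist(coords, target)
      if (abs(d - dist_target) < 0.2 && d > 2) return(coords)
    }
    stop("geometric placement infeasible after bounded retries")
  }

  n_contact <- if (n_rna > 0) contacts_per_rna * n_rna else 0
  for (r in seq_len(n_rna)) {
    for (k in seq_len(contacts_per_rna)) {
      repeat_ok <- FALSE
      for (try in 1:100) {
        coords <- place_near(rna_coords[[r]], contact_distance)
        other_ok <- TRUE
        for (r2 in seq_len(n_rna)) {
          if (r2 == r) next
          if (.set_min_dist(coords, rna_coords[[r2]]) <= 10) other_ok <- FALSE
        }
        # keep contact proteins of the same RNA apart from each other only
        # loosely; protein-protein contacts are not constrained
        if (other_ok) { repeat_ok <- TRUE; break }
      }
      if (!repeat_ok) stop("geometric placement infeasible after bounded retries")
      add_mol(coords, "protein", "ALA", "CA", "C")
    }
  }

  # bystander proteins: far from every RNA (> 10 A); in shell mode they are
  # placed on the spherical shell so radial profiles see a hollow core
  n_far <- n_protein - n_contact
  if (n_far < 0) n_far <- 0
  for (p in seq_len(n_far)) {
    if (is.null(core_inner_radius)) {
      center <- c(-120 + 30 * p, -120, 40)
      orient <- .rand_unit()
    } else {
      dir <- .rand_unit()
      center <- dir * (core_inner_radius + 8 + stats::runif(1, 0, 10))
      # tangential orientation keeps the chain off the hollow core
      orient <- .rand_unit()
      orient <- orient - sum(orient * dir) * dir
      orient <- orient / sqrt(sum(orient^2))
    }
    coords <- .bead_chain(center, orient, beads_per_molecule)
    add_mol(coords, "protein", "ALA", "CA", "C")
  }

  # crowders at a controlled distance from the protein/RNA assembly
  assembly <- do.call(rbind, mol_coords[
    vapply(mol_meta, function(m) m$kind %in% c("protein", "rna"), logical(1))])
  for (cidx in seq_len(n_crowder)) {
    if (is.null(assembly)) {
      coords <- .bead_chain(c(0, 0, 60 * cidx), .rand_unit(), 3)
    } else {
      coords <- place_near(assembly, crowder_distance, n_beads = 3)
    }
    add_mol(coords, "crowder", "PEG", "C1", "C")
  }

  # assemble atom table template
  n_mol <- length(mol_coords)
  if (n_mol == 0) stop("no molecules requested")
  atom_rows <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    co <- mol_coords[[m]]
    meta <- mol_meta[[m]]
    nb <- nrow(co)
    data.frame(atom_id = 0L, atom_name = paste0(meta$atom_name, seq_len(nb)),
               element = meta$element, residue_name = meta$resname,
               residue_id = seq_len(nb), molecule_id = m,
               molecule_kind = meta$kind,
               x = co[, 1], y = co[, 2], z = co[, 3],
               stringsAsFactors = FALSE)
  }))
  atom_rows$atom_id <- seq_len(nrow(atom_rows))

  # rigid Brownian displacement per molecule per frame (A)
  sd_step <- sqrt(2 * displacement_D * dt) * 1e4  # um -> A
  frames <- vector("list", n_frames)
  disp <- matrix(0, n_mol, 3)
  for (f in seq_len(n_frames)) {
    if (f > 1 && sd_step > 0) {
      disp <- disp + matrix(stats::rnorm(n_mol * 3, sd = sd_step), n_mol, 3)
    }
    a <- atom_rows
    sh <- disp[a$molecule_id, , drop = FALSE]
    a$x <- a$x + sh[, 1]; a$y <- a$y + sh[, 2]; a$z <- a$z + sh[, 3]
    frames[[f]] <- frame(a, time = (f - 1) * dt)
  }
  trajectory(frames, dt = dt)
}
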