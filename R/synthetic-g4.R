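# Idealized planar guanine base (Angstrom), base centroid at origin,
# base plane = xy. Derived from idealized nucleotide geometry; hydrogens
# H1/H21 are re-placed at build time to point at their Hoogsteen acceptors.
.guanine_template <- local({
  m <- matrix(c(
    -1.6004,  0.8299,   # N1
    -1.7769, -0.5208,   # C2
    -3.0531, -1.0256,   # N2
    -0.7615, -1.3544,   # N3
     0.4996, -0.9078,   # C4
     0.7465,  0.4690,   # C5
    -0.3560,  1.3549,   # C6
    -0.1865,  2.5624,   # O6
     2.0919,  0.6364,   # N7
     2.6703, -0.5294,   # C8
     1.7261, -1.5144,   # N9
     3.7380, -0.6917,   # H8
    -3.8129, -0.4229    # H22
  ), ncol = 2, byrow = TRUE)
  rownames(m) <- c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6", "N7",
                   "C8", "N9", "H8", "H22")
  m
})

# Rigid in-plane placement (tx, ty, theta) of the template guanine such that
# rotating the placed guanine by +90 deg about the quartet axis yields its
# Hoogsteen acceptor: N1...O6' and N2...N7' are both 2.90 A. Calibrated once
# by least squares; frozen here.
.quartet_placement <- c(tx = 3.83955782, ty = -2.61983737, theta = 18.18826891)

.rot2 <- function(a) matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)

#' Specification of an idealized G-quadruplex fixture
#'
#' Describes the geometry of a stack of planar G-quartets: each quartet is a
#' cycle of four guanines in which every guanine donates two Hoogsteen
#' hydrogen bonds (N1-H...O6 and N2-H...N7) to its clockwise neighbor, with
#' donor-acceptor distances of 2.90 A and perfectly linear D-H-A geometry by
#' construction.
#'
#' @param n_tetrads Number of stacked quartets (>= 1). Five emulates a
#'   tetrameric five-tetrad TERRA10 quadruplex.
#' @param topology `"tetrameric"` (4 strands, one guanine column each) or
#'   `"dimeric"` (2 strands, two columns each).
#' @param rise Stacking rise between quartet planes, Angstrom (default 3.4).
#' @param twist Helical twist per quartet step, degrees (default 30).
#' @param include_hydrogens Place imino/amino (and C8) hydrogens (default TRUE).
#' @param include_ribose Add a minimal ribose proxy (C1', O2', HO2') per
#'   guanine, for exercising 2'-hydroxyl donor overrides (default FALSE).
#' @param residue_offset Within-strand residue-index offset between
#'   vertically stacked guanines (default 6, emulating the i to i+6
#'   stacking pattern of the five-quartet TERRA10 fold).
#' @return Object of class `g4_fixture_spec`.
#' @export
g4_fixture_spec <- function(n_tetrads = 5,
                            topology = c("tetrameric", "dimeric"),
                            rise = 3.4, twist = 30,
                            include_hydrogens = TRUE,
                            include_ribose = FALSE,
                            residue_offset = 6) {
  topology <- match.arg(topology)
  if (!is.numeric(n_tetrads) || n_tetrads < 1 || n_tetrads != round(n_tetrads)) {
    stop("n_tetrads must be an integer >= 1")
  }
  structure(list(n_tetrads = as.integer(n_tetrads), topology = topology,
                 rise = rise, twist = twist,
                 include_hydrogens = include_hydrogens,
                 include_ribose = include_ribose,
                 residue_offset = as.integer(residue_offset)),
            class = "g4_fixture_spec")
}

#' Build an idealized stacked G-quadruplex frame
#'
#' Generates coordinates for `n_tetrads` stacked G-quartets with the given
#' rise and twist. Guanine base heavy atoms (N1, C2, N2, N3, C4, C5, C6, O6,
#' N7, C8, N9) are placed from a planar template; the imino H1 and one amino
#' hydrogen (H21) are directed exactly at the neighbor's O6 and N7
#' acceptors, so default Hoogsteen hydrogen-bond criteria detect exactly
#' eight bonds per quartet.
#'
#' @param spec A [g4_fixture_spec()] (or arguments passed on to it).
#' @param ... Passed to [g4_fixture_spec()] when `spec` is missing.
#' @return A [frame()] with 4 x `n_tetrads` guanine residues on 4
#'   (tetrameric) or 2 (dimeric) strands.
#' @examples
#' frm <- build_ideal_g4(g4_fixture_spec(n_tetrads = 5))
#' nrow(count_hoogsteen(trajectory(list(frm)))) # 1 frame
#' @export
build_ideal_g4 <- function(spec = g4_fixture_spec(...), ...) {
  if (!inherits(spec, "g4_fixture_spec")) stop("spec must be a g4_fixture_spec")
  n <- spec$n_tetrads
  p <- .quartet_placement
  base2d <- sweep(.guanine_template %*% t(.rot2(p[["theta"]])), 2,
                  c(p[["tx"]], p[["ty"]]), `+`)

  # columns 0..3 within each quartet level; column k donates to column k+1
  heavy <- c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6", "N7", "C8", "N9")
  rows <- list()
  for (l in seq_len(n) - 1L) {
    lev_rot <- .rot2((l * spec$twist) * pi / 180)
    z <- l * spec$rise
    placed <- lapply(0:3, function(k) {
      base2d %*% t(.rot2(k * pi / 2)) %*% t(lev_rot)
    })
    for (k in 0:3) {
      g <- placed[[k + 1]]
      nb <- placed[[(k + 1) %% 4 + 1]]
      atoms <- g[heavy, , drop = FALSE]
      if (spec$include_hydrogens) {
        h1 <- g["N1", ] + 1.01 * (nb["O6", ] - g["N1", ]) /
          sqrt(sum((nb["O6", ] - g["N1", ])^2))
        h21 <- g["N2", ] + 1.01 * (nb["N7", ] - g["N2", ]) /
          sqrt(sum((nb["N7", ] - g["N2", ])^2))
        atoms <- rbind(atoms, H1 = h1, H21 = h21,
                       H21b = g["H22", ], H8 = g["H8", ])
        rownames(atoms)[rownames(atoms) == "H21b"] <- "H22"
      }
      if (spec$include_ribose) {
        # minimal ribose proxy placed radially outward from N9, in-plane
        dir <- g["N9", ] / sqrt(sum(g["N9", ]^2))
        c1p <- g["N9", ] + 1.48 * dir
        o2p <- c1p + 1.42 * dir
        atoms <- rbind(atoms, `C1'` = c1p, `O2'` = o2p)
        if (spec$include_hydrogens) {
          atoms <- rbind(atoms, `HO2'` = o2p + 0.96 * dir)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        atom_name = rownames(atoms),
        element = substr(rownames(atoms), 1, 1),
        x = atoms[, 1], y = atoms[, 2], z = z,
        level = l, column = k,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  d <- do.call(rbind, rows)

  if (spec$topology == "tetrameric") {
    d$molecule_id <- d$column + 1L
    d$residue_id <- 1L + d$level * spec$residue_offset
  } else {
    d$molecule_id <- ifelse(d$column < 2, 1L, 2L)
    col_in_strand <- d$column %% 2L
    d$residue_id <- 1L + d$level * spec$residue_offset +
      col_in_strand * (n * spec$residue_offset + 4L)
  }
  d$residue_name <- "G"
  d$molecule_kind <- "rna"
  d$atom_id <- seq_len(nrow(d))
  frame(d[, c("atom_id", "atom_name", "element", "residue_name",
              "residue_id", "molecule_id", "molecule_kind", "x", "y", "z")])
}
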