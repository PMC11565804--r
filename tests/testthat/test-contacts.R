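test_that("engineered contact counts are recovered exactly", {
  traj <- generate_condensate_frames(n_protein = 9, n_rna = 3, n_crowder = 0,
                                     contacts_per_rna = 3, n_frames = 1,
                                     seed = 11)
  g <- contact_graph(traj$frames[[1]])
  expect_equal(unname(contact_partners(g, "rna")), rep(3L, 3))
  # a tiny cutoff empties the graph
  g0 <- contact_graph(traj$frames[[1]], contact_criteria(cutoff = 0.1))
  expect_equal(nrow(g0$edges), 0)
  # enlarging the cutoff never removes an edge (monotonicity)
  g12 <- contact_graph(traj$frames[[1]], contact_criteria(cutoff = 12))
  key <- function(e) paste(e$protein_id, e$rna_id)
  expect_true(all(key(g$edges) %in% key(g12$edges)))
})

test_that("contact edges match the all-pairs brute-force reference", {
  for (seed in 1:5) {
    traj <- generate_condensate_frames(n_protein = 3, n_rna = 2,
                                       n_crowder = 1, contacts_per_rna = 1,
                                       n_frames = 1, seed = seed)
    frm <- traj$frames[[1]]
    for (cutoff in c(5, 8, 15)) {
      got <- contact_graph(frm, contact_criteria(cutoff = cutoff))$edges
      ref <- oracle_contact_edges(frm, cutoff)
      expect_equal(got$protein_id, ref$protein_id)
      expect_equal(got$rna_id, ref$rna_id)
    }
  }
})

test_that("multivalency series summarizes bipartite degrees", {
  traj <- generate_condensate_frames(n_protein = 6, n_rna = 2, n_crowder = 0,
                                     contacts_per_rna = 3, n_frames = 5,
                                     displacement_D = 0, seed = 2)
  mv <- multivalency_series(traj)
  rna_rows <- mv[mv$side == "rna", ]
  expect_equal(rna_rows$mean_partners, rep(3, 5))  # static frames: constant
  expect_equal(rna_rows$max_partners, rep(3, 5))

  # one protein bridging 3 RNAs
  beads <- function(mol, kind, resname, cx) {
    make_atoms(atom_name = "CA", element = "C", residue_name = resname,
               residue_id = 1L, molecule_id = mol, molecule_kind = kind,
               x = cx, y = 0, z = 0)
  }
  a <- rbind(beads(1L, "protein", "ALA", 0),
             beads(2L, "rna", "G", 5), beads(3L, "rna", "G", -5),
             beads(4L, "rna", "G", 7))
  a$atom_id <- seq_len(nrow(a))
  bridged <- trajectory(list(frame(a)))
  mvb <- multivalency_series(bridged)
  expect_equal(mvb$max_partners[mvb$side == "protein"], 3)

  # frames with no protein produce all-zero distributions and a warning
  rna_only <- generate_condensate_frames(n_protein = 0, n_rna = 2,
                                         n_frames = 1, seed = 3)
  mv0 <- multivalency_series(rna_only)
  expect_true(all(mv0$mean_partners == 0))
})

test_that("crowder proximity counts molecules once, against the oracle", {
  beads <- function(mol, kind, resname, cx) {
    make_atoms(atom_name = "C1", element = "C", residue_name = resname,
               residue_id = 1L, molecule_id = mol, molecule_kind = kind,
               x = cx, y = 0, z = 0)
  }
  near <- rbind(beads(1L, "protein", "ALA", 0), beads(2L, "crowder", "PEG", 5))
  near$atom_id <- 1:2
  far <- near; far$x[2] <- 7
  expect_equal(crowder_proximity(trajectory(list(frame(near))))$count, 1L)
  expect_equal(crowder_proximity(trajectory(list(frame(far))))$count, 0L)

  for (seed in 1:4) {
    traj <- generate_condensate_frames(n_protein = 2, n_rna = 1,
                                       n_crowder = 3, contacts_per_rna = 1,
                                       n_frames = 2, displacement_D = 0.01,
                                       seed = seed)
    got <- crowder_proximity(traj)$count
    ref <- vapply(traj$frames, oracle_crowders_near, integer(1), cutoff = 6)
    expect_equal(got, ref)
  }
})

test_that("hydrogen-bond occupancy equals the per-frame indicator mean", {
  # donor residue fixed, acceptor drifts out of range halfway through
  mk_frame <- function(shift) {
    frame(make_atoms(
      atom_name = c("N", "H", "O6"),
      element = c("N", "H", "O"),
      residue_name = c("ALA", "ALA", "G"),
      residue_id = c(1L, 1L, 1L),
      molecule_id = c(1L, 1L, 2L),
      molecule_kind = c("protein", "protein", "rna"),
      x = c(0, 1, 2.9 + shift), y = 0, z = 0))
  }
  shifts <- c(rep(0, 5), rep(3, 5))
  traj <- trajectory(lapply(shifts, mk_frame))
  crit <- hbond_criteria(donor_atoms = "N", acceptor_atoms = "O6")
  occ <- hbond_occupancy(traj, crit)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occupancy, 0.5)
  expect_equal(occ$n_frames, 10)

  # always bonded -> occupancy 1; recount oracle over random trajectories
  traj1 <- trajectory(lapply(rep(0, 10), mk_frame))
  expect_equal(hbond_occupancy(traj1, crit)$occupancy, 1.0)

  frames <- lapply(1:6, function(s) {
    f <- random_hbond_frame(n_res = 8, seed = s)
    f$atoms$molecule_kind <- rep(c("protein", "rna"), length.out = 8)[
      f$atoms$molecule_id]
    f
  })
  # same atom ordering across frames: rebuild with common ids
  traj_r <- trajectory(frames)
  critg <- hbond_criteria(donor_atoms = "N1", acceptor_atoms = "O6")
  occ_r <- hbond_occupancy(traj_r, critg)
  if (nrow(occ_r) > 0) {
    for (row in seq_len(nrow(occ_r))) {
      ind <- vapply(frames, function(f) {
        hb <- oracle_hbonds(f, critg)
        don_mol <- f$atoms$molecule_id[match(hb$donor_id, f$atoms$atom_id)]
        acc_mol <- f$atoms$molecule_id[match(hb$acceptor_id, f$atoms$atom_id)]
        kinds <- f$atoms$molecule_kind[match(hb$donor_id, f$atoms$atom_id)]
        any(don_mol == occ_r$donor_molecule[row] &
              acc_mol == occ_r$acceptor_molecule[row] &
              kinds == "protein")
      }, logical(1))
      expect_equal(occ_r$occupancy[row], mean(ind))
    }
  }
})

test_that("radial density profile conserves counts and finds hollow cores", {
  # uniform ball of protein beads
  set.seed(9)
  n <- 4000
  r <- 40 * stats::runif(n)^(1 / 3)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  a <- make_atoms(atom_name = "CA", element = "C", residue_name = "ALA",
                  residue_id = 1L, molecule_id = 1L, molecule_kind = "protein",
                  x = r * u[, 1], y = r * u[, 2], z = r * u[, 3])
  prof <- radial_density_profile(frame(a), n_bins = 10, center = c(0, 0, 0),
                                 r_max = 40)
  expect_equal(sum(prof$count), n)
  inner <- prof$density[3:10]
  expect_lt(max(inner) / min(inner), 2)  # roughly flat away from edges
  expect_equal(estimate_core_diameter(prof), 0)

  # hollow shell: all atoms between 30 and 40 A
  r2 <- (30^3 + (40^3 - 30^3) * stats::runif(n))^(1 / 3)
  a2 <- a
  a2$x <- r2 * u[, 1]; a2$y <- r2 * u[, 2]; a2$z <- r2 * u[, 3]
  prof2 <- radial_density_profile(frame(a2), n_bins = 20, center = c(0, 0, 0),
                                  r_max = 40)
  core <- estimate_core_diameter(prof2)
  expect_gt(core, 52)
  expect_lt(core, 64)
  expect_error(radial_density_profile(frame(a2), n_bins = 1), "n_bins")
})
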