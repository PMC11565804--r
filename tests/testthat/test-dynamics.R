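test_that("MSD is exact for deterministic motion and invariant to rigid motion", {
  # straight line at speed v: MSD(l) = v^2 l^2
  v <- 2
  times <- seq(0, 1, 0.01)
  tr <- track(1, times, cbind(v * times, 0, 0))
  prof <- compute_msd(tr, lags = c(1, 5, 10))
  expect_equal(prof$msd, (v * prof$lag)^2, tolerance = 1e-12)

  # stationary particle
  tr0 <- track(1, times, matrix(0, length(times), 3))
  expect_true(all(compute_msd(tr0)$msd == 0))

  # global rotation + translation leaves MSD unchanged
  set.seed(1)
  pos <- apply(matrix(stats::rnorm(300), ncol = 3), 2, cumsum)
  trr <- track(1, seq_len(100) - 1, pos)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  trr2 <- track(1, seq_len(100) - 1, sweep(pos %*% R, 2, c(3, -1, 7), `+`))
  expect_equal(compute_msd(trr)$msd, compute_msd(trr2)$msd, tolerance = 1e-9)
})

test_that("Brownian ensemble MSD matches 2*dim*D*lag within sampling error", {
  D <- 0.5; dt <- 0.01
  tracks <- simulate_brownian_tracks(200, D = D, dim = 3, dt = dt,
                                     n_steps = 300, seed = 5)
  prof <- compute_msd(tracks, lags = c(1, 5, 10))
  for (i in seq_len(nrow(prof))) {
    expected <- 6 * D * prof$lag[i]
    # ~6e4 (overlapping) pairs at lag 1; 5% absorbs >3 s.e. at every lag
    expect_lt(abs(prof$msd[i] - expected) / expected, 0.05)
  }
  # per-axis step variance: 2 D dt
  steps <- do.call(rbind, lapply(tracks, function(t) diff(t$positions)))
  expect_equal(mean(steps^2), 2 * D * dt, tolerance = 0.02)

  # D = 0 freezes everything; same seed reproduces bit-exactly
  z <- simulate_brownian_tracks(3, D = 0, dim = 2, n_steps = 10, seed = 1)
  expect_true(all(vapply(z, function(t) all(t$positions == 0), logical(1))))
  a <- simulate_brownian_tracks(3, D = 1, dim = 2, n_steps = 10, seed = 9)
  b <- simulate_brownian_tracks(3, D = 1, dim = 2, n_steps = 10, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_brownian_tracks(1, D = 1, dim = 4), "dim")
})

test_that("diffusion estimates implement D = MSD/(2 dim t) and slope fits", {
  # the printed condensed-phase numbers: MSD 6.4 um^2 at 1 s, 3-D
  prof <- structure(data.frame(lag = 1, msd = 6.4, n_pairs = 100),
                    ndim = 3, class = c("msd_profile", "data.frame"))
  d <- diffusion_from_msd(prof, method = "point", at_lag = 1)
  expect_equal(d$D, 6.4 / 6, tolerance = 1e-12)

  # exact linear profile: slope and point agree exactly with the truth
  lags <- seq(0.1, 1, 0.1)
  prof2 <- structure(data.frame(lag = lags, msd = 4 * 0.5 * lags,
                                n_pairs = 100),
                     ndim = 2, class = c("msd_profile", "data.frame"))
  expect_equal(diffusion_from_msd(prof2, "slope")$D, 0.5, tolerance = 1e-12)
  expect_equal(diffusion_from_msd(prof2, "point", at_lag = 0.5)$D, 0.5,
               tolerance = 1e-12)
  expect_error(diffusion_from_msd(prof2, "point", at_lag = 0), "at_lag")
  # intercept variant tolerates an additive offset
  prof3 <- prof2
  prof3$msd <- prof3$msd + 0.3
  expect_equal(diffusion_from_msd(prof3, "slope", intercept = TRUE)$D, 0.5,
               tolerance = 1e-9)
})

test_that("per-track diffusion recovers the generating coefficient", {
  for (D in c(0.1, 0.5, 1.0)) {
    tracks <- simulate_brownian_tracks(500, D = D, dim = 2, dt = 0.01,
                                       n_steps = 100, seed = round(D * 100))
    res <- per_track_diffusion(tracks)
    expect_lt(abs(mean(res$estimates$D) - D) / D, 0.10)
  }
  # short tracks are skipped with a warning, not an error
  short <- simulate_brownian_tracks(2, D = 0.5, dim = 2, n_steps = 3, seed = 1)
  long <- simulate_brownian_tracks(3, D = 0.5, dim = 2, n_steps = 50, seed = 2)
  expect_warning(res <- per_track_diffusion(c(short, long)), "skipped")
  expect_equal(nrow(res$estimates), 3)
  expect_equal(res$n_skipped, 2)
  expect_error(per_track_diffusion(list()), "no tracks")
})

test_that("trajectory-level MSD tracks molecule centroids in micrometers", {
  traj <- generate_condensate_frames(n_protein = 4, n_rna = 0, n_frames = 60,
                                     displacement_D = 0.5, dt = 0.05, seed = 8)
  prof <- compute_msd(traj, lags = 1:5, kind = "protein")
  slope_fit <- diffusion_from_msd(prof, "slope")
  expect_lt(abs(slope_fit$D - 0.5) / 0.5, 0.6)  # 4 molecules: noisy but sane
  expect_equal(attr(prof, "ndim"), 3)
})

test_that("end-to-end distances are exact and rotation invariant", {
  mk <- function(d) {
    frame(make_atoms(atom_name = c("N", "N"), element = "N",
                     residue_name = "ALA", residue_id = c(2L, 51L),
                     molecule_id = 1L, molecule_kind = "protein",
                     x = c(0, d), y = 0, z = 0))
  }
  sel_a <- list(residue_id = 2, atom_name = "N")
  sel_b <- list(residue_id = 51, atom_name = "N")
  res <- end_to_end_distance(trajectory(list(mk(20.9), mk(20.9))),
                             sel_a, sel_b)
  expect_equal(res$mean, 20.9)
  expect_equal(res$sd, 0)

  res2 <- end_to_end_distance(trajectory(list(mk(10), mk(20))), sel_a, sel_b)
  expect_equal(res2$mean, 15)
  expect_equal(res2$sd, 5)   # population sd by convention

  rot <- trajectory(list(rotate_frame(mk(10)), rotate_frame(mk(20))))
  res3 <- end_to_end_distance(rot, sel_a, sel_b)
  expect_equal(res3$distances$distance, res2$distances$distance,
               tolerance = 1e-9)
  expect_error(end_to_end_distance(trajectory(list(mk(10))),
                                   list(residue_id = 9, atom_name = "N"),
                                   sel_b),
               "residue_id=9")
})

test_that("FRET conversions are mutually inverse and monotone", {
  expect_equal(fret_distance(0.5), 5.4)
  expect_equal(fret_efficiency(5.4), 0.5)
  r <- seq(0.5, 27, length.out = 50)   # up to 5 R0
  expect_equal(fret_distance(fret_efficiency(r)), r, tolerance = 1e-12)
  E <- seq(0.01, 0.99, length.out = 50)
  d <- fret_distance(E)
  expect_true(all(diff(d) < 0))        # higher efficiency, shorter distance
  expect_error(fret_distance(1), "E must")
  expect_error(fret_distance(0), "E must")
  expect_equal(fret_distance(0.5, R0 = 6), 6)
})
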