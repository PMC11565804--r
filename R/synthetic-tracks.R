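#' Simulate Brownian particle tracks
#'
#' Pure random-walk tracks with i.i.d. Gaussian steps of per-axis variance
#' `2 * D * dt`, so the ensemble MSD at lag `l * dt` is `2 * dim * D * l * dt`.
#' Positions are in micrometers, matching single-particle-tracking output.
#'
#' @param n_tracks Number of tracks.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param dim 2 or 3.
#' @param dt Time step, s.
#' @param n_steps Number of positions per track (>= 2).
#' @param seed Integer seed (bit-reproducible output).
#' @return List of [track()]s.
#' @export
simulate_brownian_tracks <- function(n_tracks, D, dim = 3, dt = 0.01,
                                     n_steps = 100, seed = 1) {
  if (!dim %in% c(2, 3)) stop("dim must be 2 or 3")
  if (D < 0) stop("D must be >= 0")
  if (n_steps < 2) stop("n_steps must be >= 2")
  set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  times <- (seq_len(n_steps) - 1) * dt
  lapply(seq_len(n_tracks), function(i) {
    steps <- matrix(stats::rnorm((n_steps - 1) * dim, sd = sd_step),
                    ncol = dim)
    pos <- rbind(0, apply(steps, 2, cumsum))
    if (n_steps == 2) pos <- rbind(0, matrix(steps, ncol = dim))
    track(i, times, pos)
  })
}
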