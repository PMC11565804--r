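#' Construct a particle track
#'
#' @param track_id Integer identifier.
#' @param times Strictly increasing, uniformly spaced time stamps (s).
#' @param positions n x d matrix of positions (micrometers), d = 2 or 3.
#' @return Object of class `g4_track`.
#' @export
track <- function(track_id, times, positions) {
  positions <- as.matrix(positions)
  if (!ncol(positions) %in% c(2, 3)) stop("positions must be 2- or 3-D")
  if (length(times) != nrow(positions)) stop("times/positions length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) > 2 &&
      diff(range(diff(times))) > 1e-6 * mean(diff(times))) {
    stop("times must be uniformly spaced")
  }
  structure(list(track_id = track_id, times = times, positions = positions),
            class = "g4_track")
}

# time-averaged MSD of one position matrix at integer lags
.msd_one <- function(pos, lags) {
  n <- nrow(pos)
  vapply(lags, function(l) {
    if (l >= n) return(NA_real_)
    d <- pos[(l + 1):n, , drop = FALSE] - pos[1:(n - l), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Mean squared displacement
#'
#' Time-averaged (overlapping-window) MSD, optionally ensemble-averaged over
#' tracks or molecules: MSD(l) is the mean squared displacement over all
#' ordered pairs (t, t + l). For free diffusion MSD(l) = 2 d D l.
#'
#' Input is either a list of [track()]s (positions in micrometers) or a
#' [trajectory()], in which case per-molecule centroids of the selected
#' molecule kind are tracked and coordinates are converted from Angstrom to
#' micrometers at this boundary.
#'
#' @param x List of `g4_track` (or a single track) or a `g4_trajectory`.
#' @param lags Integer lags (multiples of the time step). Default 1 to
#'   n - 1 (tracks capped at first quarter for trajectories).
#' @param averaging `"time_and_ensemble"` (one profile pooling all tracks)
#'   or `"per_track"` (list of profiles).
#' @param kind Molecule kind tracked for trajectory input (default protein).
#' @return Data frame of class `msd_profile` with `lag` (s), `msd` (um^2),
#'   `n_pairs`; attribute `ndim` carries the dimensionality. For
#'   `"per_track"`, a list of such profiles.
#' @export
compute_msd <- function(x, lags = NULL,
                        averaging = c("time_and_ensemble", "per_track"),
                        kind = "protein") {
  averaging <- match.arg(averaging)
  if (inherits(x, "g4_track")) x <- list(x)
  if (inherits(x, "g4_trajectory")) {
    x <- .centroid_tracks(x, kind)
  }
  stopifnot(length(x) >= 1)
  dt <- diff(x[[1]]$times[1:2])
  dim <- ncol(x[[1]]$positions)
  n_min <- min(vapply(x, function(t) nrow(t$positions), integer(1)))
  if (is.null(lags)) lags <- seq_len(n_min - 1)
  lags <- sort(unique(as.integer(lags)))
  drop <- lags >= n_min
  if (any(drop)) {
    warning(sum(drop), " lag(s) >= series length omitted")
    lags <- lags[!drop]
  }
  if (length(lags) == 0) stop("no usable lags")

  per <- lapply(x, function(tr) .msd_one(tr$positions, lags))
  npairs_per <- lapply(x, function(tr) pmax(nrow(tr$positions) - lags, 0L))
  mk_profile <- function(msd, n_pairs) {
    out <- data.frame(lag = lags * dt, msd = msd, n_pairs = n_pairs)
    attr(out, "ndim") <- dim
    attr(out, "dt") <- dt
    class(out) <- c("msd_profile", class(out))
    out
  }
  if (averaging == "per_track") {
    return(lapply(seq_along(x), function(i)
      mk_profile(per[[i]], npairs_per[[i]])))
  }
  w <- do.call(rbind, npairs_per)
  m <- do.call(rbind, per)
  pooled <- colSums(m * w) / colSums(w)
  mk_profile(pooled, colSums(w))
}

# per-molecule centroid tracks from a trajectory, Angstrom -> micrometer
.centroid_tracks <- function(traj, kind) {
  mols <- sort(unique(traj$frames[[1]]$atoms$molecule_id[
    traj$frames[[1]]$atoms$molecule_kind == kind]))
  if (length(mols) == 0) stop("no molecules of kind ", kind)
  times <- (seq_along(traj$frames) - 1) * traj$dt
  lapply(mols, function(m) {
    pos <- t(vapply(traj$frames, function(f) {
      colMeans(atom_xyz(f$atoms[f$atoms$molecule_id == m, , drop = FALSE]))
    }, numeric(3)))
    track(m, times, pos * 1e-4)  # 1 A = 1e-4 um
  })
}

#' Diffusion coefficient from an MSD profile
#'
#' Point estimate D = MSD(t) / (2 d t) at a single lag (the form
#' D = MSD(t)/(6t) in three dimensions), or a least-squares slope fit of
#' MSD vs lag constrained through the origin, D = slope / (2 d). An
#' unconstrained fit with an intercept (localization-noise offset) is
#' available via `intercept = TRUE`.
#'
#' @param profile An `msd_profile` from [compute_msd()].
#' @param method `"point"` or `"slope"`.
#' @param at_lag Lag time (s) for the point method (must be a profile lag).
#' @param fit_range Length-2 lag-time interval for the slope fit
#'   (default: all lags).
#' @param intercept Allow a free intercept in the slope fit (default FALSE).
#' @return List of class `diffusion_estimate`: `D` (um^2/s), `method`,
#'   `fit_range`, `stderr` (slope fits), `intercept`.
#' @export
diffusion_from_msd <- function(profile, method = c("slope", "point"),
                               at_lag = NULL, fit_range = NULL,
                               intercept = FALSE) {
  method <- match.arg(method)
  dim <- attr(profile, "ndim")
  if (method == "point") {
    if (is.null(at_lag) || at_lag == 0) stop("point method needs at_lag > 0")
    i <- which(abs(profile$lag - at_lag) < 1e-9)
    if (length(i) != 1) stop("at_lag not present in profile")
    est <- list(D = profile$msd[i] / (2 * dim * at_lag), method = "point",
                fit_range = c(at_lag, at_lag), stderr = NA_real_,
                intercept = 0)
  } else {
    keep <- if (is.null(fit_range)) rep(TRUE, nrow(profile))
            else profile$lag >= fit_range[1] & profile$lag <= fit_range[2]
    l <- profile$lag[keep]
    m <- profile$msd[keep]
    if (length(l) < 2) stop("slope fit needs >= 2 lags in range")
    if (intercept) {
      fit <- stats::lm(m ~ l)
      slope <- stats::coef(fit)[["l"]]
      se <- suppressWarnings(summary(fit)$coefficients["l", "Std. Error"])
      b <- stats::coef(fit)[[1]]
    } else {
      slope <- sum(l * m) / sum(l^2)
      resid <- m - slope * l
      se <- if (length(l) > 1)
        sqrt(sum(resid^2) / (length(l) - 1) / sum(l^2)) else NA_real_
      b <- 0
    }
    est <- list(D = slope / (2 * dim), method = "slope",
                fit_range = range(l), stderr = se / (2 * dim), intercept = b)
  }
  structure(est, class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g um^2/s (%s)\n", x$D, x$method))
  invisible(x)
}

#' Per-track diffusion coefficients
#'
#' One slope-method estimate per track from its time-averaged MSD, fitted
#' over the first `fit_fraction` of available lags (at least 2), the
#' standard single-particle-tracking reduction. Tracks shorter than 4 points
#' are skipped with a warning.
#'
#' @param tracks List of [track()]s.
#' @param fit_fraction Fraction of lags used in each fit (default 0.25).
#' @param breaks Histogram breaks passed to [hist()] (default "Sturges").
#' @return List: `estimates` (data frame `track_id`, `D`), `histogram`
#'   (a [hist()] object, not plotted), `n_skipped`.
#' @export
per_track_diffusion <- function(tracks, fit_fraction = 0.25,
                                breaks = "Sturges") {
  if (length(tracks) == 0) stop("no tracks supplied")
  ok <- vapply(tracks, function(t) nrow(t$positions) >= 4, logical(1))
  if (any(!ok)) warning(sum(!ok), " track(s) shorter than 4 points skipped")
  tracks <- tracks[ok]
  if (length(tracks) == 0) stop("no track long enough to fit")
  ests <- lapply(tracks, function(tr) {
    n <- nrow(tr$positions)
    n_lag <- max(2, floor((n - 1) * fit_fraction))
    prof <- compute_msd(tr, lags = seq_len(n_lag))
    d <- diffusion_from_msd(prof, method = "slope")
    data.frame(track_id = tr$track_id, D = d$D)
  })
  est <- do.call(rbind, ests)
  list(estimates = est,
       histogram = graphics::hist(est$D, breaks = breaks, plot = FALSE),
       n_skipped = sum(!ok))
}

#' End-to-end distance over a trajectory
#'
#' Euclidean distance between two named atoms per frame (e.g. between the
#' backbone nitrogen atoms of a protein's terminal residues), with mean and
#' standard deviation over frames. Distances are in the trajectory's length
#' unit (Angstrom).
#'
#' @param traj A [trajectory()].
#' @param atom_a,atom_b Selectors `list(residue_id =, atom_name =)`,
#'   optionally with `molecule_id`.
#' @return List: `distances` data frame (`frame`, `time`, `distance`),
#'   `mean`, `sd` (population standard deviation over frames).
#' @export
end_to_end_distance <- function(traj, atom_a, atom_b) {
  pick <- function(frm, sel) {
    a <- frm$atoms
    keep <- a$residue_id == sel$residue_id & a$atom_name == sel$atom_name
    if (!is.null(sel$molecule_id)) keep <- keep & a$molecule_id == sel$molecule_id
    hit <- a[keep, , drop = FALSE]
    if (nrow(hit) != 1) {
      stop("atom selector (residue_id=", sel$residue_id, ", atom_name=",
           sel$atom_name, ") matched ", nrow(hit), " atom(s)")
    }
    c(hit$x, hit$y, hit$z)
  }
  d <- vapply(traj$frames, function(f) {
    sqrt(sum((pick(f, atom_a) - pick(f, atom_b))^2))
  }, numeric(1))
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  list(distances = data.frame(frame = seq_along(d), time = times, distance = d),
       mean = mean(d), sd = sqrt(mean((d - mean(d))^2)))
}
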