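# assemble a fit result object
.fit_result <- function(model, parameters, stderr, derived, converged, rss) {
  structure(list(model = model, parameters = parameters, stderr = stderr,
                 derived = derived, converged = converged, rss = rss),
            class = "g4_fit")
}

#' @export
print.g4_fit <- function(x, ...) {
  cat(sprintf("<g4_fit> %s%s\n", x$model,
              if (!x$converged) " (NOT converged)" else ""))
  for (p in names(x$parameters)) {
    cat(sprintf("  %-10s %.6g (se %.3g)\n", p, x$parameters[[p]],
                x$stderr[[p]]))
  }
  for (d in names(x$derived)) {
    cat(sprintf("  %-10s %.6g\n", d, x$derived[[d]]))
  }
  cat(sprintf("  RSS %.4g\n", x$rss))
  invisible(x)
}

# extract x/y columns from a curve data frame, tolerating domain names
.curve_xy <- function(curve, xnames, ynames) {
  nm <- names(curve)
  xc <- intersect(c("x", xnames), nm)[1]
  yc <- intersect(c("y", ynames), nm)[1]
  if (is.na(xc) || is.na(yc)) stop("curve must have x/y columns")
  list(x = curve[[xc]], y = curve[[yc]])
}

#' Fit a one-site specific binding model
#'
#' Nonlinear least squares for `Y = baseline + B_max * X / (K_D + X)`.
#' `K_D` is kept positive by log-parameterization; starting values are
#' derived from the data (the concentration nearest half the signal span
#' initializes `K_D`). Unweighted by default; optional `1/Y^2` weighting.
#' An optional nonspecific linear term `NS * X` can be enabled.
#'
#' @param curve Data frame with columns `x`/`concentration` (uM, > 0) and
#'   `y`/`signal`, at least 4 distinct concentrations.
#' @param with_baseline Fit a floating baseline (default TRUE).
#' @param nonspecific Add a linear nonspecific-binding term (default FALSE).
#' @param weight_1_over_y2 Weight residuals by 1/Y^2 (default FALSE).
#' @return A `g4_fit` with parameters `K_D`, `B_max` (and `baseline`,
#'   `NS` when fitted), standard errors, convergence flag and RSS.
#' @export
fit_one_site <- function(curve, with_baseline = TRUE, nonspecific = FALSE,
                         weight_1_over_y2 = FALSE) {
  xy <- .curve_xy(curve, "concentration", c("signal", "polarization"))
  x <- xy$x; y <- xy$y
  if (length(unique(x)) < 4) stop("need >= 4 distinct concentrations")
  if (any(x <= 0)) stop("concentrations must be strictly positive")
  n_par <- 2 + with_baseline + nonspecific
  if (length(x) < n_par + 1) stop("too few points for the parameter count")

  span_mid <- min(y) + diff(range(y)) / 2
  kd0 <- x[which.min(abs(y - span_mid))]
  b0 <- diff(range(y))
  base0 <- min(y)
  w <- if (weight_1_over_y2) 1 / pmax(y^2, 1e-12) else rep(1, length(y))

  fml <- if (with_baseline && nonspecific) {
    y ~ baseline + bmax * x / (exp(lkd) + x) + ns * x
  } else if (with_baseline) {
    y ~ baseline + bmax * x / (exp(lkd) + x)
  } else if (nonspecific) {
    y ~ bmax * x / (exp(lkd) + x) + ns * x
  } else {
    y ~ bmax * x / (exp(lkd) + x)
  }
  start <- list(bmax = max(b0, 1e-9), lkd = log(max(kd0, 1e-9)))
  if (with_baseline) start$baseline <- base0
  if (nonspecific) start$ns <- 0

  fit <- tryCatch(
    suppressWarnings(
    stats::nls(fml, data = data.frame(x = x, y = y), start = start,
               weights = w,
               control = stats::nls.control(maxiter = 1000, tol = 1e-8,
                                            minFactor = 1e-12,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(.fit_result("one_site",
                       c(K_D = NA_real_, B_max = NA_real_),
                       c(K_D = NA_real_, B_max = NA_real_),
                       list(), FALSE, NA_real_))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  kd <- exp(cf[["lkd"]])
  params <- c(K_D = kd, B_max = cf[["bmax"]])
  errs <- c(K_D = kd * se[["lkd"]], B_max = se[["bmax"]])  # delta method
  if (with_baseline) {
    params["baseline"] <- cf[["baseline"]]
    errs["baseline"] <- se[["baseline"]]
  }
  if (nonspecific) {
    params["NS"] <- cf[["ns"]]; errs["NS"] <- se[["ns"]]
  }
  rss <- stats::deviance(fit)
  tss <- sum((y - mean(y))^2)
  conv <- isTRUE(fit$convInfo$isConv) || rss <= 1e-12 * max(tss, 1e-300)
  .fit_result("one_site", params, errs, list(), conv, rss)
}

#' Fit a one-phase association (FRAP recovery) model
#'
#' Nonlinear least squares for `Y = Y0 + (Plateau - Y0) * (1 - exp(-K t))`.
#' The rate `K` is kept positive by log-parameterization and initialized
#' from the time nearest half recovery. The derived recovery halftime is
#' `t_half = ln 2 / K` exactly; for a full-scale normalized curve the
#' mobile fraction is `Plateau - Y0`.
#'
#' @param curve Data frame with columns `x`/`time` (s, >= 0, increasing) and
#'   `y`/`intensity`; at least 4 points.
#' @return A `g4_fit` with parameters `K`, `Y0`, `Plateau`, derived
#'   `t_half` and `mobile_fraction`.
#' @export
fit_one_phase_association <- function(curve) {
  xy <- .curve_xy(curve, c("time", "t"), "intensity")
  t <- xy$x; y <- xy$y
  if (length(t) < 4) stop("need >= 4 points")
  if (any(t < 0) || any(diff(t) <= 0)) {
    stop("times must be non-negative and increasing")
  }
  y_half <- min(y) + diff(range(y)) / 2
  t_half0 <- t[t > 0][which.min(abs(y[t > 0] - y_half))]
  if (length(t_half0) == 0 || t_half0 <= 0) t_half0 <- stats::median(t[t > 0])
  start <- list(y0 = min(y), plateau = max(y), lk = log(log(2) / t_half0))

  fit <- tryCatch(
    suppressWarnings(
    stats::nls(y ~ y0 + (plateau - y0) * (1 - exp(-exp(lk) * t)),
               data = data.frame(t = t, y = y), start = start,
               control = stats::nls.control(maxiter = 1000, tol = 1e-8,
                                            minFactor = 1e-12,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(.fit_result("one_phase_assoc",
                       c(K = NA_real_, Y0 = NA_real_, Plateau = NA_real_),
                       c(K = NA_real_, Y0 = NA_real_, Plateau = NA_real_),
                       list(t_half = NA_real_), FALSE, NA_real_))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  K <- exp(cf[["lk"]])
  params <- c(K = K, Y0 = cf[["y0"]], Plateau = cf[["plateau"]])
  errs <- c(K = K * se[["lk"]], Y0 = se[["y0"]], Plateau = se[["plateau"]])
  rss <- stats::deviance(fit)
  tss <- sum((y - mean(y))^2)
  conv <- isTRUE(fit$convInfo$isConv) || rss <= 1e-12 * max(tss, 1e-300)
  .fit_result("one_phase_assoc", params, errs,
              list(t_half = log(2) / K,
                   mobile_fraction = cf[["plateau"]] - cf[["y0"]]),
              conv, rss)
}

#' Normalize a raw FRAP series
#'
#' Full-scale normalization: `(I(t) - I_bleach) / (I_pre - I_bleach)`, where
#' `I_pre` is the mean intensity over the prebleach window and `I_bleach`
#' the intensity at the bleach index. The clock is re-zeroed at the first
#' post-bleach point and only post-bleach points are returned.
#'
#' @param times Time stamps (s).
#' @param intensity Raw intensities.
#' @param prebleach Indices of the prebleach window (>= 1 point).
#' @param bleach_index Index of the bleach frame.
#' @return A `recovery_curve` data frame (`x` seconds from bleach, `y`
#'   normalized intensity).
#' @export
normalize_frap <- function(times, intensity, prebleach, bleach_index) {
  if (length(prebleach) < 1) stop("need at least one prebleach point")
  if (bleach_index < 1 || bleach_index > length(times)) {
    stop("bleach_index out of range")
  }
  i_pre <- mean(intensity[prebleach])
  i_bleach <- intensity[bleach_index]
  if (i_pre == i_bleach) stop("degenerate series: I_pre equals I_bleach")
  post <- bleach_index:length(times)
  out <- data.frame(x = times[post] - times[bleach_index],
                    y = (intensity[post] - i_bleach) / (i_pre - i_bleach))
  class(out) <- c("recovery_curve", class(out))
  out
}
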