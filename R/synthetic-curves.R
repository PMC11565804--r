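#' Model functions for binding and recovery curves
#'
#' `one_site_model`: specific one-site binding,
#' `Y = baseline + B_max * X / (K_D + X)`.
#' `one_phase_model`: one-phase association,
#' `Y = Y0 + (plateau - Y0) * (1 - exp(-K t))` with `K = ln 2 / t_half`.
#'
#' @param x Concentrations (uM) or times (s).
#' @param K_D,B_max,baseline One-site parameters.
#' @param t_half,Y0,plateau One-phase-association parameters.
#' @return Numeric model values.
#' @export
one_site_model <- function(x, K_D, B_max = 1, baseline = 0) {
  baseline + B_max * x / (K_D + x)
}

#' @rdname one_site_model
#' @export
one_phase_model <- function(x, t_half, Y0 = 0, plateau = 1) {
  K <- log(2) / t_half
  Y0 + (plateau - Y0) * (1 - exp(-K * x))
}

#' Generate noisy titration or recovery curves
#'
#' Evaluates the named model over `x_values` and adds Gaussian noise with
#' standard deviation `noise_sd` times the dynamic range (max - min) of the
#' noiseless values. Replicates differ only in noise.
#'
#' @param model `"one_site"` or `"one_phase_assoc"`.
#' @param parameters Named list: `K_D`, `B_max`, `baseline` for one_site;
#'   `t_half`, `Y0`, `plateau` for one_phase_assoc.
#' @param x_values Concentrations (uM, strictly positive) or times (s).
#' @param noise_sd Noise level as a fraction of the dynamic range (>= 0).
#' @param n_replicates Number of replicate curves (default 1).
#' @param seed Integer seed.
#' @return List of data frames `x`, `y` with class `titration_curve` or
#'   `recovery_curve` (a single data frame when `n_replicates = 1` would
#'   still be returned inside a length-1 list).
#' @export
generate_curves <- function(model = c("one_site", "one_phase_assoc"),
                            parameters, x_values, noise_sd = 0,
                            n_replicates = 1, seed = 1) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (model == "one_site") {
    if (any(x_values <= 0)) stop("concentrations must be strictly positive")
    mu <- one_site_model(x_values, parameters$K_D,
                         parameters$B_max %||% 1,
                         parameters$baseline %||% 0)
    cls <- "titration_curve"
  } else {
    mu <- one_phase_model(x_values, parameters$t_half,
                          parameters$Y0 %||% 0,
                          parameters$plateau %||% 1)
    cls <- "recovery_curve"
  }
  set.seed(seed)
  sd_abs <- noise_sd * diff(range(mu))
  lapply(seq_len(n_replicates), function(i) {
    y <- mu + stats::rnorm(length(mu), sd = sd_abs)
    out <- data.frame(x = x_values, y = y)
    class(out) <- c(cls, class(out))
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
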