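#' FRET efficiency / distance conversion
#'
#' Standard Foerster conversion between transfer efficiency and donor-
#' acceptor distance: `E = 1 / (1 + (r/R0)^6)` and its inverse
#' `r = R0 * (1/E - 1)^(1/6)`. The default Foerster radius of 5.4 nm is a
#' typical value for a cyanine donor-acceptor pair and is configurable.
#'
#' @param E Transfer efficiency, strictly in (0, 1).
#' @param r Donor-acceptor distance, nm (> 0).
#' @param R0 Foerster radius, nm (default 5.4).
#' @return `fret_distance`: distance in nm. `fret_efficiency`: efficiency.
#' @examples
#' fret_distance(0.5)          # = R0
#' fret_efficiency(5.4)        # = 0.5
#' @export
fret_distance <- function(E, R0 = 5.4) {
  if (any(E <= 0 | E >= 1)) stop("E must be in (0, 1)")
  if (R0 <= 0) stop("R0 must be > 0")
  R0 * (1 / E - 1)^(1 / 6)
}

#' @rdname fret_distance
#' @export
fret_efficiency <- function(r, R0 = 5.4) {
  if (any(r <= 0)) stop("r must be > 0")
  if (R0 <= 0) stop("R0 must be > 0")
  1 / (1 + (r / R0)^6)
}
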