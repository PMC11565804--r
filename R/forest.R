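#' FOREST microarray intensity normalization
#'
#' Background-corrects barcoded RNA-structure probes: the no-protein control
#' intensity is subtracted per probe, and probes sharing a structure (same
#' folded RNA, different barcodes) are averaged. Negative net intensities
#' are retained.
#'
#' @param signal Named numeric vector, probe -> protein-sample intensity.
#' @param control Named numeric vector, probe -> no-protein intensity; must
#'   cover every probe in `signal`.
#' @param barcode_map Named character vector, probe -> structure id.
#' @return Named numeric vector, structure id -> mean net intensity.
#' @export
forest_normalize <- function(signal, control, barcode_map) {
  probes <- names(signal)
  missing_ctrl <- setdiff(probes, names(control))
  if (length(missing_ctrl) > 0) {
    stop("probe(s) missing from control: ",
         paste(missing_ctrl, collapse = ", "))
  }
  missing_map <- setdiff(probes, names(barcode_map))
  if (length(missing_map) > 0) {
    stop("probe(s) missing from barcode_map: ",
         paste(missing_map, collapse = ", "))
  }
  net <- signal - control[probes]
  grp <- barcode_map[probes]
  out <- tapply(net, grp, mean)
  stats::setNames(as.numeric(out), names(out))
}
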