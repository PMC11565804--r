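#' Read a trajectory from file
#'
#' Supports two plain-text dialects: multi-model PDB (one `MODEL`/`ENDMDL`
#' block per frame, fixed columns) and the package's CSV trajectory
#' interchange format with header
#' `frame,time,atom_id,atom_name,element,residue_name,residue_id,molecule_id,molecule_kind,x,y,z`
#' (coordinates in Angstrom, one row per atom per frame, frames 0-indexed).
#'
#' For PDB input the molecule kind is inferred from residue names via
#' `kind_map`, and molecule ids from chain identifiers. All models must carry
#' identical atom counts and ordering.
#'
#' @param path File path.
#' @param format `"pdb_multimodel"` or `"csv_traj"`.
#' @param kind_map Residue-name to molecule-kind mapping (PDB only);
#'   see [default_kind_map()].
#' @param dt Frame spacing for PDB input (PDB carries no time axis);
#'   for CSV input inferred from the `time` column when possible.
#' @return A [trajectory()].
#' @export
read_frames <- function(path, format = c("pdb_multimodel", "csv_traj"),
                        kind_map = default_kind_map(), dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb_multimodel") read_pdb_multimodel(path, kind_map, dt)
  else read_csv_traj(path)
}

read_pdb_multimodel <- function(path, kind_map, dt) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- grepl("^MODEL", lines)
  # single implicit model when no MODEL records present
  model_idx <- cumsum(model_starts)
  if (!any(model_starts)) model_idx[] <- 1L
  atom_lines <- lines[is_atom]
  atom_model <- model_idx[is_atom]
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(bl) {
    nm <- trimws(substr(bl, 13, 16))
    resn <- trimws(substr(bl, 18, 20))
    chain <- substr(bl, 22, 22)
    data.frame(
      atom_id = as.integer(trimws(substr(bl, 7, 11))),
      atom_name = nm,
      element = ifelse(nzchar(trimws(substr(bl, 77, 78))),
                       trimws(substr(bl, 77, 78)),
                       substr(nm, 1, 1)),
      residue_name = resn,
      residue_id = as.integer(trimws(substr(bl, 23, 26))),
      molecule_id = match(chain, unique(chain)),
      molecule_kind = "solvent",  # placeholder, assigned below
      x = as.numeric(substr(bl, 31, 38)),
      y = as.numeric(substr(bl, 39, 46)),
      z = as.numeric(substr(bl, 47, 54)),
      stringsAsFactors = FALSE
    )
  }

  blocks <- split(atom_lines, atom_model)
  n_per <- lengths(blocks)
  if (length(unique(n_per)) != 1) {
    stop("models differ in atom count (",
         paste(unique(n_per), collapse = " vs "), "): structural error")
  }
  frames <- lapply(blocks, function(bl) {
    atoms <- parse_block(bl)
    atoms <- assign_molecule_kind(atoms, kind_map)
    frame(atoms)
  })
  for (i in seq_along(frames)) frames[[i]]$time <- (i - 1) * dt
  trajectory(unname(frames), dt = dt)
}

read_csv_traj <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "time", "atom_id", "atom_name", "element",
                "residue_name", "residue_id", "molecule_id",
                "molecule_kind", "x", "y", "z")
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) stop("csv_traj missing column(s): ",
                             paste(miss, collapse = ", "))
  fr_ids <- sort(unique(d$frame))
  frames <- lapply(fr_ids, function(f) {
    sub <- d[d$frame == f, , drop = FALSE]
    frame(sub[, setdiff(required, c("frame", "time"))], time = sub$time[1])
  })
  times <- vapply(frames, function(f) f$time, numeric(1))
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  if (!is.finite(dt) || dt <= 0) dt <- 1
  trajectory(frames, dt = dt)
}

# chain alphabet for PDB output
.pdb_chains <- c(LETTERS, letters, 0:9)

#' Write a trajectory to file
#'
#' Inverse of [read_frames()]; PDB output uses fixed columns and one
#' `MODEL`/`ENDMDL` pair per frame, so `read_frames(write_frames(t))`
#' reproduces coordinates to PDB precision (3 decimals); the CSV dialect
#' round-trips exactly.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param format `"pdb_multimodel"` or `"csv_traj"`.
#' @export
write_frames <- function(traj, path, format = c("pdb_multimodel", "csv_traj")) {
  format <- match.arg(format)
  if (!inherits(traj, "g4_trajectory") || length(traj$frames) == 0) {
    stop("trajectory must be a non-empty g4_trajectory")
  }
  if (format == "pdb_multimodel") write_pdb_multimodel(traj, path)
  else write_csv_traj(traj, path)
  invisible(NULL)
}

write_pdb_multimodel <- function(traj, path) {
  mol_ids <- unique(traj$frames[[1]]$atoms$molecule_id)
  if (length(mol_ids) > length(.pdb_chains)) {
    stop("too many molecules for PDB chain identifiers (max ",
         length(.pdb_chains), ")")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    a <- traj$frames[[i]]$atoms
    co <- c(a$x, a$y, a$z)
    if (any(co > 9999.999) || any(co < -999.999)) {
      stop("coordinate exceeds PDB fixed-column capacity ",
           "(%8.3f field: -999.999 to 9999.999 A)")
    }
    writeLines(sprintf("MODEL     %4d", i), con)
    chain <- .pdb_chains[match(a$molecule_id, mol_ids)]
    # PDB name column: 1-3 char names start in column 14
    nm <- ifelse(nchar(a$atom_name) < 4,
                 sprintf(" %-3s", a$atom_name), a$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$atom_id %% 100000, nm, substr(a$residue_name, 1, 3), chain,
      a$residue_id %% 10000, a$x, a$y, a$z, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_csv_traj <- function(traj, path) {
  rows <- lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    cbind(data.frame(frame = i - 1L, time = f$time), f$atoms)
  })
  d <- do.call(rbind, rows)
  # %.17g guarantees bit-exact double round trips through the text format
  for (col in c("time", "x", "y", "z")) {
    d[[col]] <- sprintf("%.17g", d[[col]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}
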