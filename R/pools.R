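#' Construct a read pool
#'
#' A pool of RNA reads (bind-n-seq style): the randomized regions of the
#' library, with optional constant 5'/3' adapter sequences stored alongside.
#' DNA letters (T) are mapped to U and input is uppercased.
#'
#' @param reads Character vector of reads over A/C/G/U (T accepted).
#' @param label Pool label.
#' @param adapter_5p,adapter_3p Constant adapter sequences (may be empty).
#' @return Object of class `read_pool`.
#' @export
read_pool <- function(reads, label = "", adapter_5p = "", adapter_3p = "") {
  reads <- toupper(as.character(reads))
  reads <- gsub("T", "U", reads, fixed = TRUE)
  if (any(!nzchar(reads))) stop("all reads must be non-empty")
  bad <- grepl("[^ACGU]", reads)
  if (any(bad)) stop("reads contain non-ACGU characters")
  structure(list(reads = reads, label = label,
                 adapter_5p = toupper(gsub("T", "U", adapter_5p)),
                 adapter_3p = toupper(gsub("T", "U", adapter_3p))),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf("<read_pool> '%s': %d reads, lengths %d-%d\n", x$label,
              length(x$reads), min(nchar(x$reads)), max(nchar(x$reads))))
  invisible(x)
}

#' Read a pool from FASTA/FASTQ
#'
#' FASTQ qualities are ignored; T is mapped to U.
#'
#' @param path File path.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by
#'   default.
#' @param ... Passed to [read_pool()] (label, adapters).
#' @return A [read_pool()].
#' @export
read_pool_file <- function(path, format = NULL, ...) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  seqs <- Biostrings::readBStringSet(path, format = format)
  read_pool(as.character(seqs), ...)
}

#' Write a pool to FASTA
#'
#' @param pool A [read_pool()].
#' @param path Output path.
#' @export
write_pool_fasta <- function(pool, path) {
  s <- Biostrings::BStringSet(pool$reads)
  names(s) <- sprintf("read%06d", seq_along(pool$reads))
  Biostrings::writeXStringSet(s, path)
  invisible(NULL)
}

# adapter-extended reads
.effective_reads <- function(pool, include_adapters) {
  if (include_adapters) paste0(pool$adapter_5p, pool$reads, pool$adapter_3p)
  else pool$reads
}

#' Generate matched input/bound read pools with known enrichment
#'
#' The input pool is uniform over the RNA alphabet; the bound pool is a
#' weighted resample (with replacement) of the input pool, each read
#' weighted by the product of the enrichment factors of the motifs it
#' contains (weight 1 when no motif present). A factor of 1 therefore
#' leaves the bound pool statistically identical to the input pool. Motif
#' presence is evaluated on the adapter-extended read. The reserved motif
#' name `"strong_g4"` weights reads matching the strong-G4 run/loop pattern
#' (default [pattern_spec()]) instead of a literal subsequence, emulating
#' selection by a G4-specific binder.
#'
#' @param n_reads Reads per pool (default 1e5).
#' @param read_length Randomized-region length (default 40).
#' @param enriched_motifs Named numeric vector, motif -> enrichment factor
#'   (>= 0); empty for a null library.
#' @param adapter_5p,adapter_3p Constant adapters (default empty).
#' @param pattern A [pattern_spec()] used by the reserved `"strong_g4"`
#'   motif key (default the strong-G4 pattern).
#' @param seed Integer seed.
#' @return List with elements `input_pool` and `bound_pool`
#'   (both [read_pool()]).
#' @export
generate_read_pools <- function(n_reads = 1e5, read_length = 40,
                                enriched_motifs = c(),
                                adapter_5p = "", adapter_3p = "",
                                pattern = pattern_spec(), seed = 1) {
  if (length(enriched_motifs) > 0) {
    if (is.null(names(enriched_motifs)) || any(!nzchar(names(enriched_motifs))))
      stop("enriched_motifs must be a named vector")
    literal <- setdiff(names(enriched_motifs), "strong_g4")
    if (any(nchar(literal) > read_length +
              nchar(adapter_5p) + nchar(adapter_3p)))
      stop("motif longer than the (adapter-extended) read")
    if (any(enriched_motifs < 0)) stop("enrichment factors must be >= 0")
  }
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "U"), n_reads * read_length,
                       replace = TRUE), nrow = n_reads)
  reads <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  input <- read_pool(reads, label = "input",
                     adapter_5p = adapter_5p, adapter_3p = adapter_3p)

  w <- rep(1, n_reads)
  if (length(enriched_motifs) > 0) {
    eff <- .effective_reads(input, include_adapters = TRUE)
    for (m in names(enriched_motifs)) {
      if (identical(m, "strong_g4")) {
        hit <- has_strong_g4(eff, pattern)
      } else {
        motif <- gsub("T", "U", toupper(m), fixed = TRUE)
        hit <- grepl(motif, eff, fixed = TRUE)
      }
      w[hit] <- w[hit] * enriched_motifs[[m]]
    }
  }
  idx <- sample.int(n_reads, n_reads, replace = TRUE, prob = w)
  bound <- read_pool(reads[idx], label = "bound",
                     adapter_5p = adapter_5p, adapter_3p = adapter_3p)
  list(input_pool = input, bound_pool = bound)
}
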