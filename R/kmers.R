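#' Count k-mers in a read pool
#'
#' Position-level k-mer counting: every length-k window of every read
#' contributes one instance. Frequencies are normalized over the total
#' number of instances of observed k-mers.
#'
#' @param pool A [read_pool()].
#' @param k k-mer length (default 6).
#' @param include_adapters Count over adapter-extended reads (default FALSE).
#' @return List of class `kmer_table`: `k`, `counts` (named integer vector
#'   of observed k-mers), `frequencies` (summing to 1), `total`.
#' @export
count_kmers <- function(pool, k = 6, include_adapters = FALSE) {
  reads <- .effective_reads(pool, include_adapters)
  if (k > max(nchar(reads))) stop("k exceeds every read length")
  reads <- reads[nchar(reads) >= k]
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet(reads), width = k))
  counts <- counts[counts > 0]
  total <- sum(counts)
  structure(list(k = k, counts = counts, frequencies = counts / total,
                 total = total),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %d observed k-mers, %d instances\n",
              x$k, length(x$counts), x$total))
  invisible(x)
}

#' k-mer enrichment (R statistic) between bound and input pools
#'
#' For each k-mer, R is its frequency in the protein-associated (bound)
#' pool divided by its frequency in the input pool. k-mers absent from the
#' input pool are excluded by default; `pseudocount = TRUE` instead adds one
#' count per k-mer in both pools over the full 4^k universe.
#'
#' @param bound,input [read_pool()]s.
#' @param k k-mer length (default 6).
#' @param include_adapters Count over adapter-extended reads (default FALSE).
#' @param pseudocount Apply +1 smoothing over the complete k-mer universe
#'   (default FALSE).
#' @return Data frame `kmer`, `R`, `count_bound`, `count_input`, sorted by
#'   R descending (ties broken alphabetically).
#' @export
kmer_enrichment <- function(bound, input, k = 6, include_adapters = FALSE,
                            pseudocount = FALSE) {
  tb <- count_kmers(bound, k, include_adapters)
  ti <- count_kmers(input, k, include_adapters)
  if (pseudocount) {
    universe <- Biostrings::mkAllStrings(c("A", "C", "G", "U"), k)
    cb <- stats::setNames(rep(1L, length(universe)), universe)
    ci <- cb
    cb[names(tb$counts)] <- cb[names(tb$counts)] + tb$counts
    ci[names(ti$counts)] <- ci[names(ti$counts)] + ti$counts
    fb <- cb / sum(cb); fi <- ci / sum(ci)
    kmers <- universe
  } else {
    kmers <- names(ti$counts)  # require presence in input
    cb <- stats::setNames(rep(0L, length(kmers)), kmers)
    seen <- intersect(kmers, names(tb$counts))
    cb[seen] <- tb$counts[seen]
    ci <- ti$counts
    fb <- cb / tb$total; fi <- ci / ti$total
  }
  raw_b <- if (pseudocount) cb - 1L else cb
  raw_i <- if (pseudocount) ci - 1L else ci
  out <- data.frame(kmer = kmers, R = as.numeric(fb / fi),
                    count_bound = as.integer(raw_b),
                    count_input = as.integer(raw_i),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$R, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
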