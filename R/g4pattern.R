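#' G-quadruplex motif specification
#'
#' Parametrizes the strong-G4 run/loop pattern `(G[min-max] N[0-loop])xN`:
#' `n_runs` runs of `g_run_min` to `g_run_max` consecutive guanines
#' separated by loops of 0 to `loop_max` arbitrary nucleotides. The default
#' (G3-6 N0-7)x4 is the strong-G4 pattern; `min_g_for_control` is the
#' guanine count (>= semantics) defining the G-rich non-G4 control class.
#'
#' @param g_run_min,g_run_max Guanine-run length bounds (defaults 3, 6).
#' @param loop_max Maximum loop length (default 7).
#' @param n_runs Number of runs (default 4).
#' @param min_g_for_control Guanine threshold of the non-G4 control class
#'   (default 8, counted with >= on the randomized region).
#' @return Object of class `pattern_spec`.
#' @export
pattern_spec <- function(g_run_min = 3, g_run_max = 6, loop_max = 7,
                         n_runs = 4, min_g_for_control = 8) {
  if (g_run_min < 1 || g_run_min > g_run_max) {
    stop("need 1 <= g_run_min <= g_run_max")
  }
  if (loop_max < 0) stop("loop_max must be >= 0")
  if (n_runs < 2) stop("n_runs must be >= 2")
  structure(list(g_run_min = g_run_min, g_run_max = g_run_max,
                 loop_max = loop_max, n_runs = n_runs,
                 min_g_for_control = min_g_for_control),
            class = "pattern_spec")
}

# length of the maximal G run starting at each position
.g_run_lengths <- function(chars) {
  n <- length(chars)
  run <- integer(n)
  cur <- 0L
  for (i in n:1) {
    cur <- if (chars[i] == "G") cur + 1L else 0L
    run[i] <- cur
  }
  run
}

#' Match the strong-G4 pattern in a sequence
#'
#' Existence semantics: a position matches when ANY decomposition into
#' `n_runs` G-runs (each within the run-length bounds) separated by loops of
#' at most `loop_max` nucleotides exists - loops may contain guanines and
#' runs may abut (zero-length loops), so a long G tract can supply several
#' runs. This is strictly more permissive than a greedy regular-expression
#' scan and matches the behavior of exhaustive G4 callers. Implemented as a
#' memoized backtracking scan.
#'
#' @param seq Single RNA sequence (T accepted, mapped to U).
#' @param spec A [pattern_spec()].
#' @return Data frame of maximal match spans (`start`, `end`, 1-based,
#'   inclusive); zero rows when no match.
#' @seealso [has_strong_g4()] for the boolean wrapper.
#' @export
match_strong_g4 <- function(seq, spec = pattern_spec()) {
  seq <- gsub("T", "U", toupper(seq), fixed = TRUE)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  empty <- data.frame(start = integer(), end = integer())
  if (n < spec$n_runs * spec$g_run_min) return(empty)
  run <- .g_run_lengths(chars)

  # best_end[i, r]: furthest end (1-based) of any r-run decomposition whose
  # first run starts at i; -Inf when impossible
  best <- matrix(-Inf, n, spec$n_runs)
  for (i in n:1) {
    if (run[i] < spec$g_run_min) next
    lmax <- min(spec$g_run_max, run[i])
    for (L in spec$g_run_min:lmax) {
      e <- i + L - 1L
      best[i, 1] <- max(best[i, 1], e)
      if (spec$n_runs >= 2) {
        for (r in 2:spec$n_runs) {
          js <- (e + 1L):(e + 1L + spec$loop_max)
          js <- js[js <= n]
          for (j in js) {
            if (best[j, r - 1] > -Inf) {
              best[i, r] <- max(best[i, r], best[j, r - 1])
            }
          }
        }
      }
    }
  }
  starts <- which(is.finite(best[, spec$n_runs]))
  if (length(starts) == 0) return(empty)
  ends <- best[starts, spec$n_runs]
  # keep maximal spans: drop spans contained in another span
  keep <- rep(TRUE, length(starts))
  for (i in seq_along(starts)) {
    contained <- starts <= starts[i] & ends >= ends[i] &
      (starts < starts[i] | ends > ends[i])
    if (any(contained)) keep[i] <- FALSE
  }
  data.frame(start = starts[keep], end = as.integer(ends[keep]))
}

#' Does a sequence contain a strong-G4 match?
#'
#' Vectorized boolean wrapper around [match_strong_g4()].
#'
#' @param seqs Character vector of RNA sequences.
#' @param spec A [pattern_spec()].
#' @return Logical vector.
#' @export
has_strong_g4 <- function(seqs, spec = pattern_spec()) {
  vapply(seqs, function(s) nrow(match_strong_g4(s, spec)) > 0, logical(1),
         USE.NAMES = FALSE)
}

#' Classify reads of a pool by G4 content
#'
#' Reads are labeled `strong_g4` when the strong-G4 pattern matches (by
#' default searched on the randomized region plus adapters, since adapters
#' are part of the RNA presented to the protein); `non_g4_control` when
#' there is no match but the randomized region contains at least
#' `min_g_for_control` guanines (a G-rich sequence pool lacking a defined
#' G4-forming motif); otherwise `other`.
#'
#' @param pool A [read_pool()].
#' @param spec A [pattern_spec()].
#' @param include_adapters Search the pattern on adapter-extended reads
#'   (default TRUE). The guanine count of the control rule always uses the
#'   randomized region only.
#' @return Data frame `read`, `class`; attribute `fractions` holds the
#'   per-class fractions (summing to 1).
#' @export
classify_pool <- function(pool, spec = pattern_spec(),
                          include_adapters = TRUE) {
  eff <- .effective_reads(pool, include_adapters)
  g4 <- has_strong_g4(eff, spec)
  g_count <- nchar(gsub("[^G]", "", pool$reads))
  cls <- ifelse(g4, "strong_g4",
                ifelse(g_count >= spec$min_g_for_control,
                       "non_g4_control", "other"))
  out <- data.frame(read = pool$reads, class = cls, stringsAsFactors = FALSE)
  fr <- table(factor(cls, levels = c("strong_g4", "non_g4_control", "other")))
  attr(out, "fractions") <- stats::setNames(as.numeric(fr) / length(cls),
                                            names(fr))
  out
}

#' Pattern (read-level) enrichment between bound and input pools
#'
#' The fraction of bound reads in the given class divided by the fraction of
#' input reads in that class. Classes absent from the input pool yield NA
#' with a warning.
#'
#' @param bound,input [read_pool()]s.
#' @param spec A [pattern_spec()].
#' @param class_label One of `"strong_g4"`, `"non_g4_control"`, `"other"`.
#' @param include_adapters Passed to [classify_pool()].
#' @return Single numeric enrichment ratio (NA when undefined).
#' @export
pattern_enrichment <- function(bound, input, spec = pattern_spec(),
                               class_label = "strong_g4",
                               include_adapters = TRUE) {
  fb <- attr(classify_pool(bound, spec, include_adapters), "fractions")
  fi <- attr(classify_pool(input, spec, include_adapters), "fractions")
  if (fi[[class_label]] == 0) {
    warning("class '", class_label, "' absent from the input pool; ",
            "enrichment undefined")
    return(NA_real_)
  }
  fb[[class_label]] / fi[[class_label]]
}
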