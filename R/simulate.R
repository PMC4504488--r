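# Synthetic read generation: a uniformly random reference, reads sampled as
# verbatim windows at uniform start positions, i.i.d. substitution errors at
# rate `error_rate` (to a different base) and i.i.d. N replacements at rate
# `n_rate`. Identical parameters and seed reproduce identical output.

#' Simulate a read collection
#'
#' @param ref_length Reference length `G` in bases.
#' @param n_reads Number of reads `q`.
#' @param read_length Read length `m` (at most `G`).
#' @param error_rate Per-base substitution probability in `[0, 1)`; a
#'   substituted base is drawn uniformly from the three other bases.
#' @param n_rate Per-base probability in `[0, 1)` of replacing the final
#'   symbol with `N` (applied after substitutions).
#' @param seed Optional integer seed; when given, the generator is fully
#'   deterministic.
#' @return A list with `reads` (a [read_set()]), `reference` (string) and
#'   `starts` (0-based window start per read).
#' @examples
#' sim <- simulate_reads(200, 20, 30, seed = 1)
#' sim$reads$q
#' @export
simulate_reads <- function(ref_length, n_reads, read_length,
                           error_rate = 0, n_rate = 0, seed = NULL) {
  G <- as.integer(ref_length); q <- as.integer(n_reads)
  m <- as.integer(read_length)
  if (m > G) stop("read length exceeds the reference length")
  if (q < 1L || m < 2L) stop("need at least one read of length >= 2")
  if (error_rate < 0 || error_rate >= 1 || n_rate < 0 || n_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ref_syms <- sample(bases, G, replace = TRUE)
  starts <- sample.int(G - m + 1L, q, replace = TRUE) - 1L
  reads <- vapply(starts, function(s0) {
    r <- ref_syms[(s0 + 1L):(s0 + m)]
    if (error_rate > 0) {
      err <- runif(m) < error_rate
      if (any(err))
        r[err] <- vapply(r[err], function(b)
          sample(setdiff(bases, b), 1L), character(1))
    }
    if (n_rate > 0) {
      nn <- runif(m) < n_rate
      r[nn] <- "N"
    }
    paste(r, collapse = "")
  }, character(1))
  list(reads = read_set(reads), reference = paste(ref_syms, collapse = ""),
       starts = starts)
}

#' Write a read set as FASTQ
#'
#' Emits 4-line FASTQ records named `read0`, `read1`, ... with a constant
#' quality string (`I` throughout); the package ignores qualities on input.
#'
#' @param rs A [read_set()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  x <- Biostrings::BStringSet(rs$reads)
  names(x) <- paste0("read", seq_len(rs$q) - 1L)
  qual <- Biostrings::BStringSet(rep(strrep("I", rs$m), rs$q))
  Biostrings::writeXStringSet(
    x, path, format = "fastq", qualities = qual,
    compress = endsWith(path, ".gz"))
  invisible(path)
}
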