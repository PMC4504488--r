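# Brute-force references: a sliding-window scan answering Q1-Q7 directly
# from the definitions, and an exact shortest-common-superstring solver by
# permutation enumeration. Both exist to verify the index, never to power
# it.

#' Answer the seven queries by brute force
#'
#' Slides a window over every read and collects all exact matches of `f`
#' (overlapping occurrences counted separately), then derives Q1-Q7 from
#' their definitions. Output shapes and ordering match [pg_query()]
#' exactly, so the two can be compared verbatim.
#'
#' @param rs A [read_set()].
#' @param f Pattern string, length 1 to `m`.
#' @param which One of `"Q1"`..`"Q7"` or `"all"`.
#' @return As [pg_query()].
#' @examples
#' naive_answer(read_set(c("ACAT", "CATG", "ATCA")), "CAT", "Q4")  # 2
#' @export
naive_answer <- function(rs, f, which = "all") {
  stopifnot(inherits(rs, "read_set"))
  which <- match.arg(which, c("all", .q_names))
  f <- .check_pattern(f, rs$m)
  k <- nchar(f)
  m <- rs$m
  nw <- m - k + 1L
  occ_r <- integer(0); occ_p <- integer(0)
  for (i in seq_len(rs$q)) {
    w <- substring(rs$reads[i], 1:nw, k:m)
    hit <- which(w == f)
    if (length(hit)) {
      occ_r <- c(occ_r, rep.int(i - 1L, length(hit)))
      occ_p <- c(occ_p, hit - 1L)
    }
  }
  occ <- data.frame(read_id = occ_r, pos = occ_p)   # already (read, pos) sorted
  ids <- unique(occ_r)
  n_per <- tabulate(match(occ_r, ids), nbins = length(ids))
  q5 <- ids[n_per == 1L]
  q7 <- occ[occ$read_id %in% q5, , drop = FALSE]
  rownames(q7) <- NULL
  res <- list(Q1 = ids, Q2 = length(ids), Q3 = occ, Q4 = nrow(occ),
              Q5 = q5, Q6 = length(q5), Q7 = q7)
  if (which == "all") res else res[[which]]
}

# all permutations of 1..n as a list (n <= 7 here)
.perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(.perms(n - 1L), function(p) c(i, p + (p >= i)))
  }))
}

#' Exact shortest common superstring of a few strings
#'
#' Enumerates all orderings of the (deduplicated) input strings and
#' left-folds each, merging consecutive strings with their maximal
#' suffix-prefix overlap; returns the minimum-length result. For
#' equal-length strings (where containment implies equality, removed by
#' the deduplication) this enumeration is exact. Factorial cost, hence the
#' instance-size cap.
#'
#' @param reads Character vector of strings.
#' @param max_q Largest number of distinct strings accepted (default 7).
#' @return A list with `length` and one optimal `superstring`.
#' @examples
#' brute_force_scs(c("ACAT", "CATG", "ATCA"))$length  # 8
#' @export
brute_force_scs <- function(reads, max_q = 7L) {
  reads <- unique(toupper(as.character(reads)))
  n <- length(reads)
  if (n == 0L) stop("no input strings")
  if (n > max_q) stop("instance too large for exact solver")
  if (n == 1L) return(list(length = nchar(reads), superstring = reads))
  best <- NULL
  for (p in .perms(n)) {
    s <- reads[p[1L]]
    for (i in 2:n) {
      y <- reads[p[i]]
      l <- max_overlap(s, y)
      s <- paste0(s, substr(y, l + 1L, nchar(y)))
    }
    if (is.null(best) || nchar(s) < nchar(best)) best <- s
  }
  list(length = nchar(best), superstring = best)
}
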