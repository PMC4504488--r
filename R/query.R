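# Query answering: binary search over the suffix array (seeded by the LUT),
# backward scan over the placement array to enumerate all reads containing a
# hit, then per-read aggregation for the seven queries.
#
# Q1: reads containing f         Q2: |Q1|
# Q3: (read, position) occurrences of f   Q4: |Q3|
# Q5: reads containing f exactly once     Q6: |Q5|
# Q7: the single occurrence in each Q5 read
#
# The engine is functional: per-query state lives in local variables, so
# the transient occurrence / single-occurrence placement flags stay FALSE
# before and after every call (the classical flag-and-stack device is an
# optimization for mutable implementations, not part of the semantics).
# The repetitive-read flag is used for real: for patterns at least as long
# as the flag mer length, an unflagged read cannot contain the pattern
# twice, so its single-occurrence status needs no counting.

.check_pattern <- function(f, m) {
  if (length(f) != 1L || !is.character(f) || is.na(f) || nchar(f) == 0L)
    stop("empty query pattern")
  f <- toupper(f)
  if (grepl("[^ACGTN]", f)) stop("invalid symbol in query pattern")
  if (nchar(f) > m) stop("query longer than read")
  f
}

# smallest 1-based SA rank in [lo, hi] whose length-|pat| suffix prefix
# compares >= pat (strict = FALSE) or > pat (strict = TRUE)
.sa_bound <- function(pgs, pos, lo, hi, pat, strict) {
  kp <- nchar(pat)
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    chunk <- substr(pgs, pos[mid] + 1L, pos[mid] + kp)
    gt <- if (strict) chunk > pat else chunk >= pat
    if (gt) hi <- mid - 1L else lo <- mid + 1L
  }
  lo
}

# maximal half-open interval [lo, hi) of SA ranks whose suffixes start with
# pat, seeded by the LUT when the pattern covers the LUT prefix
.sa_interval <- function(idx, pat, sa = idx$sa) {
  n <- length(sa$pos)
  lo <- 1L; hi <- n
  lut <- idx$lut
  kp <- nchar(pat)
  if (idx$pg$sigma == 4L && grepl("N", pat, fixed = TRUE))
    return(c(1L, 0L))                 # N never occurs in a 4-letter index
  if (!is.null(lut) && kp >= lut$l) {
    r <- sum(.sym_ranks(substr(pat, 1L, lut$l), lut$sigma) *
               lut$sigma^((lut$l - 1L):0)) + 1
    cnt <- lut$count[r]
    if (cnt == 0L) return(c(1L, 0L))
    lo <- lut$first[r]; hi <- lo + cnt - 1L
    if (kp == lut$l) return(c(lo, hi + 1L))
  }
  a <- .sa_bound(idx$pg$pg, sa$pos, lo, hi, pat, strict = FALSE)
  b <- .sa_bound(idx$pg$pg, sa$pos, a, hi, pat, strict = TRUE)
  c(a, b)
}

#' Locate the pseudogenome occurrences of a pattern
#'
#' Dense index: one binary search (seeded by the LUT) returning the maximal
#' suffix array interval whose suffixes start with `f`; the hit positions
#' are the entries' start positions. Sparse index with sparsity `s`: for
#' each shift `r` in `0..min(s,k)-1` the sampled array is searched for
#' `f[r+1..k]`, and a sampled entry is accepted when its cached preceding
#' symbols end with `f[1..r]`; the occurrence then starts `r` symbols
#' before the sampled position. Every occurrence is found under exactly one
#' shift.
#'
#' @param idx A `pg_index`.
#' @param f Pattern (length `>= s` on a sparse index; exactly `fixed_k` on
#'   a fixed-k index).
#' @return A list with `pos` (0-based pseudogenome start positions of all
#'   occurrences, in suffix-array rank order per shift), `shift` (the shift
#'   `r` that produced each hit; all 0 on a dense index) and, for a dense
#'   index, `range` (the half-open 1-based SA rank interval `c(lo, hi)`).
#' @export
locate_range <- function(idx, f) {
  stopifnot(inherits(idx, "pg_index"))
  f <- .check_pattern(f, idx$pg$m)
  k <- nchar(f)
  if (idx$fixed_k > 0L && k != idx$fixed_k)
    stop("index is specialized to fixed k = ", idx$fixed_k)
  if (idx$s == 1L) {
    iv <- .sa_interval(idx, f)
    hits <- if (iv[2L] > iv[1L]) idx$sa$pos[iv[1L]:(iv[2L] - 1L)]
            else integer(0)
    return(list(pos = hits, shift = integer(length(hits)), range = iv))
  }
  if (k < idx$s) stop("query shorter than sparsity")
  pos <- integer(0); shift <- integer(0)
  for (r in 0:(min(idx$s, k) - 1L)) {
    iv <- .sa_interval(idx, substr(f, r + 1L, k))
    if (iv[2L] <= iv[1L]) next
    ranks <- iv[1L]:(iv[2L] - 1L)
    if (r > 0L) {
      pre <- idx$sa$cached_prefix[ranks]   # s-1 preceding symbols, '-'-padded
      want <- substr(f, 1L, r)
      ok <- substr(pre, idx$s - r, idx$s - 1L) == want
      ranks <- ranks[ok]
    }
    if (length(ranks)) {
      pos <- c(pos, idx$sa$pos[ranks] - r)
      shift <- c(shift, rep.int(r, length(ranks)))
    }
  }
  list(pos = pos, shift = shift)
}

#' Enumerate read occurrences of pseudogenome hits
#'
#' For each pseudogenome position `t` at which the pattern starts, the
#' furthest placement covering `t` is inspected first: if the pattern
#' crosses that read's end it crosses every covering read's end (earlier
#' placements only increase the in-read offset) and the hit yields nothing.
#' Otherwise the placement array is scanned backward, emitting
#' `(read ID, t - offset)` while the pattern still fits inside the read.
#'
#' @param idx A `pg_index`.
#' @param pos 0-based pseudogenome hit positions (from [locate_range()]).
#' @param k Pattern length.
#' @return Data frame with 0-based columns `read_id`, `pos`, in hit order
#'   then placement index descending (unsorted; [pg_query()] normalizes).
#' @export
enumerate_occurrences <- function(idx, pos, k) {
  pg <- idx$pg
  offs <- pg$offsets; ids <- pg$orig_ids; m <- pg$m
  out_r <- integer(0); out_p <- integer(0)
  for (t in pos) {
    j <- findInterval(t, offs)
    while (j >= 1L && t - offs[j] + k <= m) {
      out_r <- c(out_r, ids[j])
      out_p <- c(out_p, t - offs[j])
      j <- j - 1L
    }
  }
  data.frame(read_id = out_r, pos = out_p)
}

.q_names <- paste0("Q", 1:7)

#' Answer the seven read-indexing queries
#'
#' @param idx A `pg_index`.
#' @param f Pattern string over `{A,C,G,T,N}` (N matches only N), of length
#'   1 to `m`; at least `s` on a sparse index; exactly `fixed_k` on a
#'   fixed-k index.
#' @param which One of `"Q1"`..`"Q7"` or `"all"`.
#' @return For `"Q1"`/`"Q5"`: sorted integer vector of 0-based read IDs.
#'   For `"Q2"`/`"Q4"`/`"Q6"`: a count. For `"Q3"`/`"Q7"`: a data frame
#'   `(read_id, pos)` sorted by read then position, 0-based. For `"all"`: a
#'   named list of all seven.
#' @examples
#' idx <- build_index(read_set(c("ACAT", "CATG", "ATCA")))
#' pg_query(idx, "CAT", "all")
#' @export
pg_query <- function(idx, f, which = "all") {
  stopifnot(inherits(idx, "pg_index"))
  which <- match.arg(which, c("all", .q_names))
  f <- .check_pattern(f, idx$pg$m)
  # counting queries served from the cache when possible
  if (which %in% c("Q2", "Q4", "Q6") && idx$fixed_k == 0L &&
      nchar(f) >= idx$s) {
    v <- cache_lookup(idx$cache, f, which)
    if (!is.null(v)) return(v)
  }
  k <- nchar(f)
  hits <- locate_range(idx, f)
  occ <- enumerate_occurrences(idx, hits$pos, k)
  o <- order(occ$read_id, occ$pos)
  occ <- occ[o, , drop = FALSE]
  rownames(occ) <- NULL
  res <- .aggregate_queries(idx, occ, k)
  if (which == "all") res else res[[which]]
}

.aggregate_queries <- function(idx, occ, k) {
  ids <- unique(occ$read_id)               # ascending: occ sorted by read
  n_per <- tabulate(match(occ$read_id, ids), nbins = length(ids))
  single <- if (k >= idx$flag_len) {
    # unflagged reads cannot contain a pattern this long twice
    rep_f <- idx$rep_flags[ids + 1L]
    !rep_f | n_per == 1L
  } else {
    n_per == 1L
  }
  q5 <- ids[single]
  q7 <- occ[occ$read_id %in% q5 & !duplicated(occ$read_id), , drop = FALSE]
  rownames(q7) <- NULL
  list(Q1 = ids, Q2 = length(ids), Q3 = occ, Q4 = nrow(occ),
       Q5 = q5, Q6 = length(q5), Q7 = q7)
}

#' Resolve a positional query to its pattern string
#'
#' A query may be given as `(read ID, start, length)` instead of an
#' explicit string; it denotes the substring
#' `read[start .. start+k)` (0-based) of that read, and every downstream
#' answer is identical to the sequence form.
#'
#' @param x A [read_set()] or `pg_index`.
#' @param read_id 0-based read ID.
#' @param start 0-based start position within the read.
#' @param k Pattern length; `start + k <= m`.
#' @return The pattern string.
#' @examples
#' rs <- read_set(c("ACAT", "CATG", "ATCA"))
#' resolve_positional(rs, 1, 0, 3)  # "CAT"
#' @export
resolve_positional <- function(x, read_id, start, k) {
  rs <- if (inherits(x, "pg_index")) pg_reads(x) else x
  stopifnot(inherits(rs, "read_set"))
  read_id <- as.integer(read_id); start <- as.integer(start)
  k <- as.integer(k)
  if (is.na(read_id) || read_id < 0L || read_id >= rs$q)
    stop("read ID out of range")
  if (is.na(start) || start < 0L || is.na(k) || k < 1L ||
      start + k > rs$m)
    stop("positional query outside the read")
  substr(rs$reads[read_id + 1L], start + 1L, start + k)
}
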