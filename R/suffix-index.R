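# Suffix array over the pseudogenome, with read-relative entries, optional
# sparsification, a prefix lookup table (LUT), per-read repetitive flags and
# small-k count caches.

# Prefix-doubling (Manber-Myers) suffix sort over integer symbol codes.
# Returns 1-based start positions of the suffixes in lexicographic order
# (shorter-is-smaller on exhaustion, since absent symbols rank below all
# real ones). O(p log^2 p) with radix ordering; ample at the scales this
# package targets.
.suffix_order <- function(codes) {
  n <- length(codes)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  rk <- match(codes, sort(unique(codes)))
  h <- 1L
  repeat {
    key2 <- if (h >= n) integer(n) else c(rk[(h + 1L):n], integer(h))
    o <- order(rk, key2, method = "radix")
    r1 <- rk[o]; r2 <- key2[o]
    rk[o] <- cumsum(c(1L, as.integer(r1[-1L] != r1[-n] | r2[-1L] != r2[-n])))
    if (rk[o[n]] == n) break
    h <- h * 2L
  }
  order(rk)
}

#' Build the dense suffix array of a pseudogenome
#'
#' One entry per pseudogenome position, in lexicographic order of the
#' suffixes (A < C < G < N < T; a proper prefix sorts before its
#' extensions). Entries are stored in read-relative coordinates: the index
#' of the *furthest* placement covering the suffix start (the placement
#' with the largest offset not exceeding it; ties between co-located
#' duplicate reads resolved toward the later placement) and the 0-based
#' offset of the suffix start within that read.
#'
#' @param pg A `pseudogenome` from [build_pseudogenome()].
#' @return An object of class `pg_suffix_array`: `pos` (0-based PG start
#'   positions in lexicographic suffix order), `place` (1-based placement
#'   index per entry), `off` (0-based in-read offset per entry), sparsity
#'   `s = 1`, `cached_prefix = NULL`.
#' @export
build_suffix_array <- function(pg) {
  stopifnot(inherits(pg, "pseudogenome"))
  codes <- .sym_codes(pg$pg)
  pos <- .suffix_order(codes) - 1L
  sa <- structure(list(pos = pos, s = 1L, cached_prefix = NULL),
                  class = "pg_suffix_array")
  attach_read_coordinates(sa, pg)
}

#' Attach read-relative coordinates to suffix array entries
#'
#' Maps each suffix start position to `(placement index, in-read offset)`
#' with the placement index maximal; the mapping is inverted exactly by
#' `offsets[place] + off`.
#'
#' @param sa A `pg_suffix_array` (its `pos` field is used).
#' @param pg The `pseudogenome` the array was built over.
#' @return The suffix array with `place` and `off` filled in.
#' @export
attach_read_coordinates <- function(sa, pg) {
  place <- findInterval(sa$pos, pg$offsets)   # rightmost offset <= pos
  off <- sa$pos - pg$offsets[place]
  stopifnot(all(off >= 0L), all(off < pg$m))
  sa$place <- place
  sa$off <- off
  sa
}

#' Sparsify a suffix array
#'
#' Retains only the entries whose pseudogenome position is divisible by the
#' sparsity `s` (0-based; position 0 is always sampled), preserving their
#' lexicographic order, and caches for each sampled entry the `s - 1`
#' symbols immediately preceding it in the pseudogenome. Positions before
#' the start of the text are padded with `-`, a sentinel that matches
#' nothing. The cached symbols let pattern hits that start up to `s - 1`
#' symbols before a sampled position be verified without touching the
#' pseudogenome string.
#'
#' @param sa A dense (`s = 1`) `pg_suffix_array`.
#' @param s Target sparsity, 2 to 6.
#' @param pg The underlying `pseudogenome`.
#' @return A sparse `pg_suffix_array` with `cached_prefix` (one
#'   `(s-1)`-character string per entry).
#' @export
sparsify <- function(sa, s, pg) {
  stopifnot(inherits(sa, "pg_suffix_array"))
  if (sa$s != 1L) stop("sparsify expects a dense suffix array")
  s <- as.integer(s)
  if (s < 2L || s > 6L) stop("sparsity must be between 2 and 6")
  keep <- sa$pos %% s == 0L
  pos <- sa$pos[keep]
  lo <- pos - s + 1L
  pre <- substring(pg$pg, pmax(lo, 0L) + 1L, pos)  # up to s-1 preceding chars
  pad <- strrep("-", pmax(0L, -lo))
  sa$pos <- pos
  sa$place <- sa$place[keep]
  sa$off <- sa$off[keep]
  sa$s <- s
  sa$cached_prefix <- paste0(pad, pre)
  sa
}

#' Number of lookup-table entries
#'
#' `sigma^l` cells, one per possible length-`l` prefix over the alphabet.
#' With the classical choice `l = 11` this is `4^11` or `5^11`, both under
#' 50 million.
#'
#' @param sigma Alphabet size (4 or 5).
#' @param l Prefix length.
#' @return The entry count, as a double.
#' @export
lut_entry_count <- function(sigma, l) as.numeric(sigma)^l

#' Build the prefix lookup table
#'
#' For every possible length-`l` prefix, the half-open interval of suffix
#' array ranks whose suffixes start with that prefix (suffixes shorter than
#' `l` belong to no interval; a pattern of length >= `l` can never match
#' them). Binary searches for patterns of length >= `l` are confined to the
#' interval of the pattern's own `l`-prefix.
#'
#' @param sa A `pg_suffix_array` (dense or sparse).
#' @param pg The underlying `pseudogenome`.
#' @param l Prefix length; default adapts to the pseudogenome size,
#'   `min(11, floor(log_sigma(max(p, 2))))` (at least 1).
#' @return An object of class `pg_lut`: `l`, `sigma`, `first` (1-based SA
#'   rank of the first entry per prefix, 0 when empty), `count` (interval
#'   widths).
#' @export
build_lookup_table <- function(sa, pg, l = NULL) {
  sigma <- pg$sigma
  if (is.null(l))
    l <- max(1L, min(11L, as.integer(floor(log(max(pg$p, 2)) / log(sigma)))))
  l <- as.integer(l)
  if (l < 1L) stop("LUT prefix length must be >= 1")
  n_cells <- lut_entry_count(sigma, l)
  if (n_cells > 2^26)
    stop("LUT of ", n_cells, " cells exceeds the configured memory budget")
  n_cells <- as.integer(n_cells)
  # 0-based rank of the length-l prefix of each entry's suffix (NA if short)
  n <- length(sa$pos)
  first <- integer(n_cells); count <- integer(n_cells)
  if (n > 0L) {
    long_enough <- sa$pos + l <= pg$p
    pref <- substring(pg$pg, sa$pos + 1L, sa$pos + l)
    rk <- rep(NA_integer_, n)
    if (any(long_enough))
      rk[long_enough] <- vapply(
        pref[long_enough],
        function(s) sum(.sym_ranks(s, sigma) * sigma^((l - 1L):0)),
        numeric(1), USE.NAMES = FALSE)
    idx <- which(!is.na(rk))
    if (length(idx)) {
      r <- rk[idx]                      # nondecreasing along SA order
      starts <- idx[!duplicated(r)]
      first[unique(r) + 1L] <- starts
      count <- tabulate(r + 1L, nbins = n_cells)
    }
  }
  structure(list(l = l, sigma = sigma, first = first, count = count),
            class = "pg_lut")
}

#' Per-read repetitive flags
#'
#' Flag a read when at least one of its length-`l` substrings occurs two or
#' more times within the read (occurrences may overlap). A query of length
#' `>= l` can occur more than once in a read only if the read is flagged,
#' which lets the single-occurrence queries skip per-read counting for
#' unflagged reads.
#'
#' @param rs A [read_set()].
#' @param l Mer length (default 11). When `l > m` no `l`-mer exists and all
#'   flags are `FALSE`.
#' @return Logical vector of length `q`.
#' @export
compute_repetitive_flags <- function(rs, l = 11L) {
  stopifnot(inherits(rs, "read_set"))
  l <- as.integer(l)
  if (l > rs$m) return(logical(rs$q))
  vapply(rs$reads, function(r) {
    w <- substring(r, 1:(nchar(r) - l + 1L), l:nchar(r))
    anyDuplicated(w) > 0L
  }, logical(1), USE.NAMES = FALSE)
}
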