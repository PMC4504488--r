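# Assembly of the full query index: pseudogenome + suffix array + LUT +
# repetitive-read flags + optional count caches, with a fixed-k
# specialization that prunes suffixes crossing read boundaries.

#' Build a read index
#'
#' Constructs the pseudogenome, its (optionally sparse) suffix array with
#' read-relative coordinates, the prefix lookup table, per-read repetitive
#' flags, and optional precomputed count caches.
#'
#' @param rs A [read_set()].
#' @param sparsity Suffix array sparsity `s`, 1 (dense) to 6. Queries on a
#'   sparse index require pattern length `k >= s`.
#' @param lut_len LUT prefix length; `NULL` adapts it to the pseudogenome
#'   size (see [build_lookup_table()]).
#' @param cache_max_k Cache exact Q2/Q4/Q6 answers for all ACGT k-mers with
#'   `k` up to this bound (0 disables; capped at `m`).
#' @param cache_ext_k Additionally cache, for `cache_max_k < k <=
#'   cache_ext_k`, a single narrow value valid only when `Q2 = Q4 = Q6` and
#'   below the cell's sentinel (see [precompute_count_cache()]).
#' @param ext_cell_bytes Cell width of the extended cache, 1 or 2 bytes
#'   (sentinel `2^8 - 1` or `2^16 - 1`).
#' @param fixed_k 0 for the variable-length-query index; a positive value
#'   prunes every suffix whose `k`-prefix crosses a read boundary, after
#'   which only queries of exactly that length are supported. Requires
#'   `sparsity = 1`.
#' @param flag_len Mer length of the repetitive-read flags (default 11).
#' @return An object of class `pg_index`.
#' @examples
#' idx <- build_index(read_set(c("ACAT", "CATG", "ATCA")), cache_max_k = 2)
#' pg_query(idx, "CAT", "Q2")  # 2
#' @export
build_index <- function(rs, sparsity = 1L, lut_len = NULL, cache_max_k = 8L,
                        cache_ext_k = 0L, ext_cell_bytes = 2L, fixed_k = 0L,
                        flag_len = 11L) {
  stopifnot(inherits(rs, "read_set"))
  sparsity <- as.integer(sparsity)
  if (sparsity < 1L || sparsity > 6L)
    stop("sparsity must be between 1 and 6")
  fixed_k <- as.integer(fixed_k)
  if (fixed_k > 0L && sparsity > 1L)
    stop("fixed-k pruning requires a dense (sparsity 1) index")
  pg <- build_pseudogenome(rs)
  sa <- build_suffix_array(pg)
  idx <- structure(
    list(pg = pg, sa = sa, lut = NULL, s = 1L, fixed_k = 0L,
         rep_flags = compute_repetitive_flags(rs, flag_len),
         flag_len = as.integer(flag_len),
         occ_flags = logical(rs$q), single_flags = logical(rs$q),
         cache = NULL, lut_len = lut_len),
    class = "pg_index")
  if (fixed_k > 0L) {
    idx$lut <- build_lookup_table(sa, pg, lut_len)   # prune_fixed_k rebuilds
    idx <- prune_fixed_k(idx, fixed_k)
  } else {
    if (sparsity > 1L) {
      idx$sa <- sparsify(sa, sparsity, pg)
      idx$s <- sparsity
    }
    idx$lut <- build_lookup_table(idx$sa, pg, lut_len)
  }
  cache_max_k <- min(as.integer(cache_max_k), rs$m)
  if (cache_max_k > 0L)
    idx$cache <- precompute_count_cache(rs, cache_max_k,
                                        as.integer(cache_ext_k),
                                        as.integer(ext_cell_bytes))
  idx
}

#' @export
print.pg_index <- function(x, ...) {
  cat(sprintf(
    paste0("pg_index: q = %d reads (m = %d, sigma = %d), p = %d, ",
           "%d SA entries (s = %d)%s, LUT l = %d\n"),
    x$pg$q, x$pg$m, x$pg$sigma, x$pg$p, length(x$sa$pos), x$s,
    if (x$fixed_k > 0L) sprintf(", fixed k = %d", x$fixed_k) else "",
    x$lut$l))
  invisible(x)
}

#' Reconstruct the reads stored in an index
#'
#' The index is self-contained: each read is recovered from the
#' pseudogenome through its placement.
#'
#' @param idx A `pg_index`.
#' @return A [read_set()] with reads in original ID order.
#' @export
pg_reads <- function(idx) {
  stopifnot(inherits(idx, "pg_index"))
  pg <- idx$pg
  seqs <- character(pg$q)
  seqs[pg$orig_ids + 1L] <-
    substring(pg$pg, pg$offsets + 1L, pg$offsets + pg$m)
  read_set(seqs)
}

#' Placement flag table
#'
#' The per-placement flag byte: the build-time repetitive-read flag and the
#' two transient query flags (occurrence, single-occurrence). The query
#' engine leaves the transient flags `FALSE` on entry and exit of every
#' query.
#'
#' @param idx A `pg_index`.
#' @return Data frame with columns `read_id`, `repetitive`, `occurrence`,
#'   `single_occurrence`, one row per placement (in placement order).
#' @export
placement_flags <- function(idx) {
  stopifnot(inherits(idx, "pg_index"))
  ids <- idx$pg$orig_ids
  data.frame(read_id = ids,
             repetitive = idx$rep_flags[ids + 1L],
             occurrence = idx$occ_flags[ids + 1L],
             single_occurrence = idx$single_flags[ids + 1L])
}

#' Specialize an index to a fixed query length
#'
#' Removes from the (dense) suffix array every entry whose length-`k`
#' prefix is not fully contained in a read, i.e. whose in-read offset
#' satisfies `offset + k > m` for its furthest placement (earlier
#' placements only increase the offset, so containment in the furthest read
#' is equivalent to containment in any). After pruning, every entry of a
#' pattern's SA range contributes at least one occurrence, so the range
#' width never exceeds `|Q3|`. The LUT is rebuilt over the surviving
#' entries.
#'
#' @param idx A dense, variable-length `pg_index`.
#' @param k The fixed query length, `1 <= k <= m`.
#' @return The pruned index; [pg_query()] then accepts only length-`k`
#'   patterns.
#' @export
prune_fixed_k <- function(idx, k) {
  stopifnot(inherits(idx, "pg_index"))
  if (idx$s != 1L) stop("fixed-k pruning requires a dense (sparsity 1) index")
  if (idx$fixed_k > 0L) stop("index is already in fixed-k mode")
  k <- as.integer(k)
  if (k > idx$pg$m) stop("query longer than read")
  if (k < 1L) stop("fixed k must be >= 1")
  keep <- idx$sa$off + k <= idx$pg$m
  idx$sa$pos <- idx$sa$pos[keep]
  idx$sa$place <- idx$sa$place[keep]
  idx$sa$off <- idx$sa$off[keep]
  idx$fixed_k <- k
  idx$lut <- build_lookup_table(idx$sa, idx$pg, idx$lut_len)
  idx
}

# ---------------------------------------------------------------------------
# Count caches. For k up to a base bound, full arrays of the three counting
# answers (Q2: reads containing the k-mer, Q4: total occurrences, Q6: reads
# containing it exactly once), indexed by the k-mer's base-4 rank over
# ACGT. For the extended range a single narrow array stores the common
# value only when Q2 = Q4 = Q6 and it is below the sentinel (the cell's
# maximum representable value); the sentinel signals "not cached" and the
# live query path is used instead. Only ACGT k-mers are cached; windows or
# queries containing N always take the live path.

#' Precompute count caches
#'
#' @param rs A [read_set()].
#' @param base_max_k Full Q2/Q4/Q6 arrays for `1 <= k <= base_max_k`.
#' @param ext_max_k Narrow common-value arrays for
#'   `base_max_k < k <= ext_max_k` (0 disables).
#' @param ext_cell_bytes 1 or 2; the sentinel is `2^(8*bytes) - 1`.
#' @return An object of class `pg_count_cache`.
#' @export
precompute_count_cache <- function(rs, base_max_k, ext_max_k = 0L,
                                   ext_cell_bytes = 2L) {
  stopifnot(inherits(rs, "read_set"))
  base_max_k <- as.integer(base_max_k)
  ext_max_k <- as.integer(ext_max_k)
  if (!ext_cell_bytes %in% c(1L, 2L))
    stop("extended cache cells must be 1 or 2 bytes")
  if (base_max_k < 1L) stop("base_max_k must be >= 1")
  top_k <- max(base_max_k, ext_max_k)
  if (top_k > rs$m) stop("cache bound exceeds the read length")
  sentinel <- 2^(8L * ext_cell_bytes) - 1
  tables <- vector("list", base_max_k)
  ext <- if (ext_max_k > base_max_k) vector("list", ext_max_k) else NULL
  # 0..3 codes per read, NA at N positions; computed once for all k
  codes <- lapply(rs$reads, function(r) {
    x <- .sym_codes(r)
    x[x == 4L] <- NA_integer_            # N
    x - (x == 5L) - 1L                   # A,C,G -> 0,1,2 ; T -> 3
  })
  for (k in seq_len(top_k)) {
    cnt <- .kmer_read_counts(codes, rs$q, rs$m, k)  # per (k-mer rank, read)
    nb <- as.integer(4^k)
    q4 <- tabulate(rep.int(cnt$rank + 1L, cnt$n), nbins = nb)
    q2 <- tabulate(cnt$rank + 1L, nbins = nb)
    q6 <- tabulate(cnt$rank[cnt$n == 1L] + 1L, nbins = nb)
    if (k <= base_max_k) {
      tables[[k]] <- list(q2 = q2, q4 = q4, q6 = q6)
    } else {
      v <- q2
      v[!(q2 == q4 & q4 == q6 & q2 < sentinel)] <- sentinel
      ext[[k]] <- v
    }
  }
  structure(list(base_max_k = base_max_k, ext_max_k = ext_max_k,
                 ext_cell_bytes = as.integer(ext_cell_bytes),
                 sentinel = sentinel, tables = tables, ext = ext),
            class = "pg_count_cache")
}

# per-(k-mer, read) occurrence counts over ACGT k-mers only;
# `codes` holds one 0..3/NA integer vector per read
.kmer_read_counts <- function(codes, q, m, k) {
  nw <- m - k + 1L
  pow <- 4^((k - 1L):0)
  rank <- unlist(lapply(codes, function(x) {
    Reduce(`+`, lapply(seq_len(k), function(j) x[j:(j + nw - 1L)] * pow[j]))
  }), use.names = FALSE)
  rid <- rep(seq_len(q) - 1L, each = nw)
  ok <- !is.na(rank)                     # windows containing N drop out
  rank <- rank[ok]; rid <- rid[ok]
  if (!length(rank)) return(list(rank = integer(0), n = integer(0)))
  pair <- rank * q + rid
  up <- sort(unique(pair))
  n <- tabulate(match(pair, up), nbins = length(up))
  list(rank = floor(up / q), n = n)
}

#' Cached counting-query lookup
#'
#' Returns the cached `Q2`/`Q4`/`Q6` answer for an N-free ACGT pattern, or
#' `NULL` when the pattern is outside the cache bounds, contains `N`, or
#' hits the extended cache's sentinel -- in which case the caller falls back
#' to the live query path.
#'
#' @param cache A `pg_count_cache` (or `NULL`).
#' @param f Pattern string.
#' @param which `"Q2"`, `"Q4"` or `"Q6"`.
#' @return Integer count or `NULL`.
#' @export
cache_lookup <- function(cache, f, which) {
  if (is.null(cache)) return(NULL)
  k <- nchar(f)
  if (grepl("N", f, fixed = TRUE)) return(NULL)
  top <- max(cache$base_max_k, cache$ext_max_k)
  if (k > top) return(NULL)
  rank <- sum(.sym_ranks(f, 4L) * 4^((k - 1L):0))
  if (k <= cache$base_max_k) {
    t <- cache$tables[[k]]
    return(switch(which, Q2 = t$q2, Q4 = t$q4, Q6 = t$q6)[rank + 1L])
  }
  v <- cache$ext[[k]][rank + 1L]
  if (v >= cache$sentinel) NULL else v
}
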