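# Versioned binary index container (".pgsa"): fixed-width little-endian
# integers, sections in declared order -- header, packed pseudogenome,
# placements, suffix array entries, LUT, count caches. Fields derivable
# from stored sections (suffix positions, sparse cached symbols, the
# transient query flags) are reconstructed on load, so a round trip is
# byte-identical.

.PGSA_MAGIC <- charToRaw("PGSA")
.PGSA_VERSION <- 1L

.wi <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                 endian = "little")
.wu8 <- function(con, x) writeBin(as.raw(x), con)
.wi16 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                   endian = "little")

.ri <- function(con, n) {
  x <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(x) != n) stop("truncated index container")
  x
}
.ru8 <- function(con, n) {
  x <- readBin(con, "raw", n = n)
  if (length(x) != n) stop("truncated index container")
  as.integer(x)
}
.ri16 <- function(con, n) {
  x <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
               endian = "little")
  if (length(x) != n) stop("truncated index container")
  x
}

# densest packing variant valid for sigma (1-byte units)
.pg_density <- function(sigma) if (sigma == 4L) 4L else 3L

#' Serialize an index to a .pgsa container
#'
#' @param idx A `pg_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_index()]
#' @export
write_index <- function(idx, path) {
  stopifnot(inherits(idx, "pg_index"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  pg <- idx$pg
  writeBin(.PGSA_MAGIC, con)
  .wu8(con, .PGSA_VERSION)
  .wu8(con, pg$sigma)
  .wu8(con, idx$s)
  .wi(con, c(pg$q, pg$m, pg$p, idx$fixed_k, idx$flag_len))
  # packed pseudogenome
  d <- .pg_density(pg$sigma)
  packed <- pack_sequence(pg$pg, density = d, unit_bytes = 1L,
                          sigma = pg$sigma)
  .wu8(con, d)
  .wi(con, length(packed$payload))
  writeBin(packed$payload, con)
  # placements: offsets, original IDs, flag bytes (bit 0: repetitive)
  .wi(con, pg$offsets)
  .wi(con, pg$orig_ids)
  .wu8(con, as.integer(idx$rep_flags[pg$orig_ids + 1L]))
  # suffix array entries in read-relative form
  .wi(con, length(idx$sa$place))
  .wi(con, idx$sa$place)
  .wi16(con, idx$sa$off)
  # LUT
  .wi(con, c(idx$lut$l, length(idx$lut$first)))
  .wi(con, idx$lut$first)
  .wi(con, idx$lut$count)
  # count caches
  if (is.null(idx$cache)) {
    .wu8(con, 0L)
  } else {
    ch <- idx$cache
    .wu8(con, 1L)
    .wi(con, c(ch$base_max_k, ch$ext_max_k))
    .wu8(con, ch$ext_cell_bytes)
    for (k in seq_len(ch$base_max_k)) {
      t <- ch$tables[[k]]
      .wi(con, t$q2); .wi(con, t$q4); .wi(con, t$q6)
    }
    if (ch$ext_max_k > ch$base_max_k) {
      for (k in (ch$base_max_k + 1L):ch$ext_max_k) {
        if (ch$ext_cell_bytes == 1L) .wu8(con, ch$ext[[k]])
        else .wi16(con, ifelse(ch$ext[[k]] > 32767, ch$ext[[k]] - 65536,
                               ch$ext[[k]]))
      }
    }
  }
  invisible(path)
}

#' Load an index from a .pgsa container
#'
#' Validates the magic number and format version, then reconstructs the
#' full in-memory index; a loaded index answers every query identically to
#' the one serialized.
#'
#' @param path Path to a file written by [write_index()].
#' @return A `pg_index`.
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, .PGSA_MAGIC)) stop("not a .pgsa container")
  ver <- .ru8(con, 1L)
  if (ver != .PGSA_VERSION) stop("unsupported .pgsa version ", ver)
  sigma <- .ru8(con, 1L)
  s <- .ru8(con, 1L)
  hdr <- .ri(con, 5L)
  q <- hdr[1L]; m <- hdr[2L]; p <- hdr[3L]
  fixed_k <- hdr[4L]; flag_len <- hdr[5L]
  d <- .ru8(con, 1L)
  n_payload <- .ri(con, 1L)
  payload <- readBin(con, "raw", n = n_payload)
  if (length(payload) != n_payload) stop("truncated index container")
  packed <- structure(list(payload = payload, length = p, density = d,
                           unit_bytes = 1L, sigma = sigma),
                      class = "packed_seq")
  pg_str <- unpack_sequence(packed)
  offsets <- .ri(con, q)
  orig_ids <- .ri(con, q)
  flag_bytes <- .ru8(con, q)
  pg <- structure(
    list(pg = pg_str, p = p, m = m, q = q, sigma = sigma,
         offsets = offsets, orig_ids = orig_ids),
    class = "pseudogenome")
  n_sa <- .ri(con, 1L)
  place <- .ri(con, n_sa)
  off <- .ri16(con, n_sa)
  pos <- offsets[place] + off
  sa <- structure(list(pos = pos, place = place, off = off, s = s,
                       cached_prefix = NULL),
                  class = "pg_suffix_array")
  if (s > 1L) {
    lo <- pos - s + 1L
    pre <- substring(pg_str, pmax(lo, 0L) + 1L, pos)
    sa$cached_prefix <- paste0(strrep("-", pmax(0L, -lo)), pre)
  }
  lut_hdr <- .ri(con, 2L)
  lut <- structure(
    list(l = lut_hdr[1L], sigma = sigma,
         first = .ri(con, lut_hdr[2L]), count = .ri(con, lut_hdr[2L])),
    class = "pg_lut")
  rep_flags <- logical(q)
  rep_flags[orig_ids + 1L] <- flag_bytes %% 2L == 1L
  cache <- NULL
  if (.ru8(con, 1L) == 1L) {
    ck <- .ri(con, 2L)
    cell <- .ru8(con, 1L)
    sentinel <- 2^(8L * cell) - 1
    tables <- vector("list", ck[1L])
    for (k in seq_len(ck[1L])) {
      nb <- as.integer(4^k)
      tables[[k]] <- list(q2 = .ri(con, nb), q4 = .ri(con, nb),
                          q6 = .ri(con, nb))
    }
    ext <- NULL
    if (ck[2L] > ck[1L]) {
      ext <- vector("list", ck[2L])
      for (k in (ck[1L] + 1L):ck[2L]) {
        nb <- as.integer(4^k)
        v <- if (cell == 1L) .ru8(con, nb)
             else { x <- .ri16(con, nb); x + 65536 * (x < 0L) }
        ext[[k]] <- v
      }
    }
    cache <- structure(
      list(base_max_k = ck[1L], ext_max_k = ck[2L], ext_cell_bytes = cell,
           sentinel = sentinel, tables = tables, ext = ext),
      class = "pg_count_cache")
  }
  structure(
    list(pg = pg, sa = sa, lut = lut, s = s, fixed_k = fixed_k,
         rep_flags = rep_flags, flag_len = flag_len,
         occ_flags = logical(q), single_flags = logical(q),
         cache = cache, lut_len = lut$l),
    class = "pg_index")
}
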