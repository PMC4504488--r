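# Read collection parsing, alphabet detection and DNA symbol packing.
#
# The collation order used throughout the package is ASCII order of the
# uppercase symbols: A < C < G < N < T. The alphabet has 4 symbols (ACGT) or
# 5 (ACGTN); sigma = 5 exactly when at least one N occurs in the input.

.PG_SYMBOLS <- c("A", "C", "G", "N", "T")

# integer codes 1..5 (A=1 ... T=5) for one string; NA for foreign symbols
.sym_codes <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  match(strsplit(s, "", fixed = TRUE)[[1L]], .PG_SYMBOLS)
}

# 0-based rank of each symbol of `s` within an alphabet of size sigma
# (sigma = 4: A,C,G,T -> 0..3; sigma = 5: A,C,G,N,T -> 0..4)
.sym_ranks <- function(s, sigma) {
  syms <- if (sigma == 4L) c("A", "C", "G", "T") else .PG_SYMBOLS
  r <- match(strsplit(s, "", fixed = TRUE)[[1L]], syms)
  if (anyNA(r)) stop("symbol outside the ", sigma, "-letter alphabet")
  r - 1L
}

#' Construct a read set from character sequences
#'
#' Validates and normalizes a collection of equal-length DNA reads over
#' `{A,C,G,T}` or `{A,C,G,T,N}`. Lowercase letters are uppercased; any other
#' symbol is an error. Reads keep their input order and are addressed by
#' 0-based IDs `0..q-1` everywhere in the package.
#'
#' @param reads Character vector of sequences, all of the same length
#'   (at least 2 symbols).
#' @param ids Optional record names used only in error messages.
#' @return An object of class `read_set` with elements `reads` (character),
#'   `q` (number of reads), `m` (read length) and `sigma` (alphabet size,
#'   4 or 5).
#' @examples
#' rs <- read_set(c("ACAT", "CATG", "ATCA"))
#' rs$q; rs$m; rs$sigma
#' @export
read_set <- function(reads, ids = NULL) {
  if (length(reads) < 1L) stop("empty read collection")
  reads <- toupper(as.character(reads))
  lens <- nchar(reads)
  if (length(unique(lens)) != 1L) stop("variable-length reads unsupported")
  m <- lens[[1L]]
  if (m < 2L) stop("reads must have at least 2 symbols")
  bad <- grep("[^ACGTN]", reads)
  if (length(bad)) {
    nm <- if (!is.null(ids)) ids[bad[1L]] else paste0("#", bad[1L] - 1L)
    stop("invalid symbol in record ", nm)
  }
  sigma <- if (any(grepl("N", reads, fixed = TRUE))) 5L else 4L
  structure(
    list(reads = reads, q = length(reads), m = m, sigma = sigma),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: q = %d reads of length m = %d, sigma = %d\n",
              x$q, x$m, x$sigma))
  invisible(x)
}

#' Load a read collection from FASTA or FASTQ
#'
#' Reads all sequences from a FASTA or 4-line FASTQ file (transparently
#' gunzipped when the file is gzip-compressed), uppercases them, and
#' validates that all reads have equal length over `{A,C,G,T,N}`. FASTQ
#' quality strings are ignored. Record IDs `0..q-1` are assigned in order of
#' appearance.
#'
#' @param path Path to the reads file.
#' @param format `"auto"` (sniff the first record marker), `"fasta"` or
#'   `"fastq"`.
#' @return A [read_set()].
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    if (length(first) == 0L) stop("empty reads file: ", path)
    format <- if (startsWith(first, "@")) "fastq"
              else if (startsWith(first, ">")) "fasta"
              else stop("cannot detect FASTA/FASTQ format of ", path)
  }
  seqs <- Biostrings::readBStringSet(path, format = format)
  if (length(seqs) == 0L) stop("empty reads file: ", path)
  read_set(as.character(seqs), ids = names(seqs))
}

#' Detect the alphabet of a read set
#'
#' The alphabet is `ACGT` (size 4) unless at least one `N` occurs anywhere in
#' the collection, in which case it is `ACGTN` (size 5). Depends only on the
#' multiset of symbols present.
#'
#' @param rs A [read_set()].
#' @return A list with `symbols` (in collation order) and `sigma`.
#' @export
detect_alphabet <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (rs$sigma == 5L) list(symbols = .PG_SYMBOLS, sigma = 5L)
  else list(symbols = c("A", "C", "G", "T"), sigma = 4L)
}

# ---------------------------------------------------------------------------
# Symbol packing. Variants: 2, 3 or 4 symbols per byte, or 4, 5 or 6 symbols
# per 2-byte unit. A variant is valid when sigma^density fits the unit
# (sigma = 4 admits all six variants; sigma = 5 admits 2-3 per byte and
# 4-6 per 2-byte unit). The final partial unit is padded with the alphabet's
# first symbol (A); the true symbol count is retained.

.pack_valid <- function(sigma, density, unit_bytes) {
  if (unit_bytes == 1L && !(density %in% 2:4)) return(FALSE)
  if (unit_bytes == 2L && !(density %in% 4:6)) return(FALSE)
  as.numeric(sigma)^density <= 2^(8L * unit_bytes)
}

#' Pack a DNA string into bytes
#'
#' Stores `density` symbols per storage unit (1- or 2-byte), each unit
#' holding the base-`sigma` value of its symbols (first symbol least
#' significant). Lossless: [unpack_sequence()] restores the input exactly.
#'
#' @param s A string over the alphabet.
#' @param density Symbols per unit: 2-4 for 1-byte units, 4-6 for 2-byte.
#' @param unit_bytes Storage unit size in bytes (1 or 2).
#' @param sigma Alphabet size (4 or 5); default: 5 if `s` contains `N`.
#' @return An object of class `packed_seq`: `payload` (raw vector,
#'   little-endian units), `length` (symbol count), `density`, `unit_bytes`,
#'   `sigma`.
#' @export
pack_sequence <- function(s, density = 4L, unit_bytes = 1L, sigma = NULL) {
  stopifnot(length(s) == 1L, is.character(s))
  s <- toupper(s)
  if (is.null(sigma))
    sigma <- if (grepl("N", s, fixed = TRUE)) 5L else 4L
  density <- as.integer(density); unit_bytes <- as.integer(unit_bytes)
  if (!.pack_valid(sigma, density, unit_bytes))
    stop("packing density ", density, "/", unit_bytes,
         "-byte unit is incompatible with sigma = ", sigma)
  ranks <- .sym_ranks(s, sigma)
  len <- length(ranks)
  n_units <- ceiling(len / density)
  if (n_units > 0L) {
    ranks <- c(ranks, integer(n_units * density - len))  # pad with 'A' (rank 0)
    mat <- matrix(ranks, nrow = density)
    vals <- as.numeric(colSums(mat * sigma^(seq_len(density) - 1L)))
  } else {
    vals <- numeric(0)
  }
  payload <- if (unit_bytes == 1L) {
    as.raw(vals)
  } else {
    as.raw(as.vector(rbind(vals %% 256, vals %/% 256)))
  }
  structure(
    list(payload = payload, length = len, density = density,
         unit_bytes = unit_bytes, sigma = as.integer(sigma)),
    class = "packed_seq"
  )
}

#' Unpack a packed DNA sequence
#'
#' @param p A `packed_seq` from [pack_sequence()].
#' @return The original symbol string.
#' @export
unpack_sequence <- function(p) {
  stopifnot(inherits(p, "packed_seq"))
  if (p$length == 0L) return("")
  vals <- if (p$unit_bytes == 1L) {
    as.integer(p$payload)
  } else {
    b <- as.integer(p$payload)
    b[c(TRUE, FALSE)] + 256L * b[c(FALSE, TRUE)]
  }
  d <- p$density
  ranks <- as.vector(vapply(seq_len(d) - 1L,
                            function(j) (vals %/% p$sigma^j) %% p$sigma,
                            numeric(length(vals))))
  # vapply above gives units x d; interleave back to symbol order
  ranks <- as.vector(t(matrix(ranks, ncol = d)))
  syms <- if (p$sigma == 4L) c("A", "C", "G", "T") else .PG_SYMBOLS
  paste(syms[ranks[seq_len(p$length)] + 1L], collapse = "")
}
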