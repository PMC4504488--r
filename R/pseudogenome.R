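# Greedy pseudogenome construction.
#
# The pseudogenome is a superstring of all q reads, obtained by a multi-pass
# greedy merge: after an initial lexicographic sort and a duplicate-collapsing
# phase, overlap lengths are tried from m-1 down to 1. In the pass for
# overlap length l, the reads whose suffix is still free (no successor
# assigned), ordered by their suffix of length l, are co-traversed with the
# reads whose prefix is still free (no predecessor), in lexicographic order
# of the read -- like the merge step of merge sort, but looking for equal
# keys (suffix of one read == prefix of another). A match chains the two
# reads; a per-chain "head" registry rejects matches that would close a
# cycle, so the successor relation always forms vertex-disjoint simple
# paths. Finally each chain is written out head-to-tail honoring the
# recorded overlaps, chains in lexicographic order of their head read,
# concatenated with zero overlap.
#
# This is the classic greedy heuristic for the (NP-hard) shortest common
# superstring problem restricted to equal-length strings; it guarantees
# m <= p <= q*m, not optimality.

#' Maximal suffix-prefix overlap of two strings
#'
#' Largest `l` such that the last `l` symbols of `x` equal the first `l`
#' symbols of `y` (`0` when no overlap exists; `min(nchar(x), nchar(y))`
#' at most, so two identical strings overlap fully).
#'
#' @param x,y Strings.
#' @return Integer overlap length.
#' @examples
#' max_overlap("ACAT", "CATG")  # 3
#' max_overlap("ACAT", "ATCA")  # 2
#' @export
max_overlap <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  for (l in seq.int(min(nx, ny), 1L)) {
    if (substr(x, nx - l + 1L, nx) == substr(y, 1L, l)) return(l)
  }
  0L
}

# One merge pass at exact overlap length l over the builder state.
# state fields: succ, ov, has_succ, has_pred (per read), head_of (valid for
# chain tails), tail_of (valid for chain heads), S, Q (ID vectors).
.match_overlaps <- function(state, l, reads) {
  S <- state$S; Q <- state$Q
  ns <- length(S); nq <- length(Q)
  if (ns == 0L || nq == 0L) return(state)
  m <- nchar(reads[[1L]])
  # S ordered by the suffix of length l (starting at position m - l,
  # 0-based); ties broken by full read then ID for determinism
  skeys <- substr(reads[S], m - l + 1L, m)
  so <- order(skeys, reads[S], S, method = "radix")
  S <- S[so]; skeys <- skeys[so]
  # Q is kept in lexicographic read order; its keys are length-l prefixes
  qkeys <- substr(reads[Q], 1L, l)

  s_taken <- logical(ns); q_taken <- logical(nq)
  si <- 1L; qi <- 1L
  while (si <= ns && qi <= nq) {
    sk <- skeys[si]; qk <- qkeys[qi]
    if (sk < qk) { si <- si + 1L; next }
    if (sk > qk) { qi <- qi + 1L; next }
    # equal-key block: pair greedily, first-in-Q-order wins, skipping
    # self-matches and matches that would close a cycle
    s_end <- si; while (s_end < ns && skeys[s_end + 1L] == sk) s_end <- s_end + 1L
    q_end <- qi; while (q_end < nq && qkeys[q_end + 1L] == sk) q_end <- q_end + 1L
    for (a in si:s_end) {
      x <- S[a]
      hx <- state$head_of[x]
      for (b in qi:q_end) {
        if (q_taken[b]) next
        y <- Q[b]
        if (y == x || y == hx) next  # self or cycle-closing candidate
        state$succ[x] <- y
        state$ov[x] <- l
        state$has_succ[x] <- TRUE
        state$has_pred[y] <- TRUE
        tb <- state$tail_of[y]          # y is the head of its chain
        state$head_of[tb] <- hx
        state$tail_of[hx] <- tb
        s_taken[a] <- TRUE; q_taken[b] <- TRUE
        break
      }
    }
    si <- s_end + 1L; qi <- q_end + 1L
  }
  state$S <- S[!s_taken]       # unmatched suffixes carry to the next pass
  state$Q <- Q[!q_taken]       # unmatched prefixes, still in lex order
  state
}

# Duplicate phase: consecutive identical reads in the sorted order chain
# with overlap m (placement delta 0).
.dedup_phase <- function(state, ord, reads, m) {
  q <- length(ord)
  if (q >= 2L) {
    for (j in 2:q) {
      x <- ord[j - 1L]; y <- ord[j]
      if (reads[x] == reads[y] && !state$has_succ[x] && !state$has_pred[y]) {
        state$succ[x] <- y; state$ov[x] <- m
        state$has_succ[x] <- TRUE; state$has_pred[y] <- TRUE
        hx <- state$head_of[x]; tb <- state$tail_of[y]
        state$head_of[tb] <- hx
        state$tail_of[hx] <- tb
      }
    }
  }
  state$S <- ord[!state$has_succ[ord]]
  state$Q <- ord[!state$has_pred[ord]]
  state
}

#' Build a pseudogenome from a read set
#'
#' Runs the greedy overlap-merging construction: lexicographic sort,
#' duplicate collapsing, then one matching pass per overlap length from
#' `m - 1` down to `1`. Deterministic for a given read set.
#'
#' @param rs A [read_set()].
#' @return An object of class `pseudogenome` with elements `pg` (the
#'   superstring), `p` (its length), `m`, `sigma`, and the placement vectors
#'   `offsets` (0-based start of each read in `pg`, nondecreasing) and
#'   `orig_ids` (0-based original read IDs, a permutation of `0..q-1`).
#'   Placement `i` satisfies `substr(pg, offsets[i]+1, offsets[i]+m) ==
#'   rs$reads[orig_ids[i]+1]`.
#' @examples
#' pg <- build_pseudogenome(read_set(c("ACAT", "CATG", "ATCA")))
#' pg$p   # 8: both overlaps are found
#' @export
build_pseudogenome <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  reads <- rs$reads; q <- rs$q; m <- rs$m
  state <- list(
    succ = rep(NA_integer_, q), ov = rep(NA_integer_, q),
    has_succ = logical(q), has_pred = logical(q),
    head_of = seq_len(q), tail_of = seq_len(q),
    S = integer(0), Q = integer(0)
  )
  ord <- order(reads, seq_len(q), method = "radix")
  state <- .dedup_phase(state, ord, reads, m)
  if (m >= 2L) {
    for (l in seq.int(m - 1L, 1L)) {
      state <- .match_overlaps(state, l, reads)
      if (length(state$S) == 0L || length(state$Q) == 0L) break
    }
  }
  # emit chains, heads in lexicographic order (ties by ID)
  heads <- which(!state$has_pred)
  heads <- heads[order(reads[heads], heads, method = "radix")]
  offsets <- integer(q); orig <- integer(q)
  parts <- character(q)
  idx <- 0L; off <- 0L
  for (h in heads) {
    cur <- h
    idx <- idx + 1L
    offsets[idx] <- off; orig[idx] <- cur
    parts[idx] <- reads[cur]
    while (state$has_succ[cur]) {
      nxt <- state$succ[cur]; l <- state$ov[cur]
      off <- off + (m - l)
      idx <- idx + 1L
      offsets[idx] <- off; orig[idx] <- nxt
      parts[idx] <- substr(reads[nxt], l + 1L, m)
      cur <- nxt
    }
    off <- off + m
  }
  stopifnot(idx == q)
  pg <- paste(parts, collapse = "")
  structure(
    list(pg = pg, p = nchar(pg), m = m, q = q, sigma = rs$sigma,
         offsets = offsets, orig_ids = orig - 1L),
    class = "pseudogenome"
  )
}

#' @export
print.pseudogenome <- function(x, ...) {
  cat(sprintf(
    "pseudogenome: p = %d symbols from q = %d reads of length m = %d (p/(q*m) = %.3f)\n",
    x$p, x$q, x$m, x$p / (x$q * x$m)))
  invisible(x)
}

#' Check a pseudogenome against its read set
#'
#' Verifies every structural invariant: first placement at offset 0, last at
#' `p - m`, consecutive offset deltas in `0..m` (so every position is
#' covered by a read), original IDs a permutation of `0..q-1`,
#' `m <= p <= q*m`, and each placed read reproduced character for character.
#' Never raises; failures are reported as diagnostics.
#'
#' @param pg A `pseudogenome`.
#' @param rs The [read_set()] it was built from.
#' @return `TRUE`, or `FALSE` with a `diagnostics` attribute (character
#'   vector naming each violated invariant).
#' @export
verify_pseudogenome <- function(pg, rs) {
  bad <- character(0)
  add <- function(msg) bad <<- c(bad, msg)
  q <- rs$q; m <- rs$m; p <- pg$p
  if (length(pg$offsets) != q) add("placement count != q")
  if (p < m || p > q * m) add(sprintf("p = %d outside [m, q*m]", p))
  if (length(pg$offsets) == q && q >= 1L) {
    if (pg$offsets[1L] != 0L) add("first placement not at offset 0")
    if (pg$offsets[q] != p - m) add("last placement not at offset p - m")
    if (q >= 2L) {
      d <- diff(pg$offsets)
      if (any(d < 0L)) add("placements not sorted by offset")
      if (any(d > m)) add(sprintf("coverage gap after placement %d",
                                  which(d > m)[1L] - 1L))
    }
    if (!identical(sort(pg$orig_ids), 0:(q - 1L)))
      add("original IDs are not a permutation of 0..q-1")
    placed <- substring(pg$pg, pg$offsets + 1L, pg$offsets + m)
    want <- rs$reads[pg$orig_ids + 1L]
    mism <- which(placed != want)
    if (length(mism))
      add(sprintf("placement %d does not reproduce read %d",
                  mism[1L] - 1L, pg$orig_ids[mism[1L]]))
  }
  if (length(bad)) structure(FALSE, diagnostics = bad) else TRUE
}

#' Text dump of read placements
#'
#' Debug view: one line per placement, `offset TAB read-ID TAB sequence`.
#'
#' @param pg A `pseudogenome`.
#' @return Character vector of lines (invisibly printed when interactive).
#' @export
placement_dump <- function(pg) {
  sprintf("%d\t%d\t%s", pg$offsets, pg$orig_ids,
          substring(pg$pg, pg$offsets + 1L, pg$offsets + pg$m))
}
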