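---
title: "Pseudogenome suffix array indexing: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudogenome suffix array indexing: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsuffix)
```

## The model

The input is a collection $\mathcal{R} = [R_1, \dots, R_q]$ of reads of a
common length $m \ge 2$ over the alphabet $\{A,C,G,T\}$ or
$\{A,C,G,T,N\}$; $\sigma \in \{4,5\}$ is detected in a preliminary pass
($\sigma = 5$ exactly when an `N` occurs). Collation is ASCII order,
$A < C < G < N < T$.

A *pseudogenome* is a string $PG[0..p)$ together with placements
$(j_1, u_1), \dots, (j_q, u_q)$ such that $j_1 = 0$, $j_q = p - m$,
$j_{i+1} - j_i \in \{0, \dots, m\}$, $[u_1..u_q]$ is a permutation of the
read IDs, and $PG[j_i .. j_i + m) = R_{u_i}$ for all $i$. The delta
condition guarantees every text position is covered by at least one read,
and $m \le p \le qm$. Minimizing $p$ is the shortest common superstring
problem, which is NP-hard; the builder is a greedy heuristic.

### Greedy construction

The builder maintains, per read, an overlap record (successor ID and
overlap length once assigned), and two worklists: $S$, the reads with no
successor yet, and $Q$, the reads with no predecessor yet, the latter kept
in lexicographic read order. After sorting the reads lexicographically
(ties by input ID), a *duplicate phase* chains runs of identical reads with
overlap $m$ (placement delta 0). The main loop then tries overlap lengths
$\ell = m-1$ down to $1$: $S$ is ordered by the length-$\ell$ suffix of its
reads and co-traversed with $Q$ the way two sorted arrays are merged, but
looking for key equality — the suffix of an $S$-read equal to the prefix of
a $Q$-read. Within a block of equal keys, each $S$-read takes the first
available $Q$-read that is neither itself nor the head of its own chain;
that *chain-head exclusion* (each chain tail knows its head, updated in
$O(1)$ per merge) keeps the successor relation a union of vertex-disjoint
simple paths — no cycles, ever. Unmatched entries carry over to the next
pass. Finally chains are emitted head-to-tail honoring the recorded
overlaps, in lexicographic order of their head read, concatenated with zero
overlap.

Two choices here were genuinely open and are ours: the within-block
tie-break (first in $Q$'s lexicographic-then-ID order) and the inter-chain
emission order (lexicographic by head). Both affect the text content of
$PG$, neither affects validity, $p$, or any query answer.

On the instructive instance $\{ACAT, CATG, ATCA\}$ the greedy pass at
$\ell=3$ joins $ACAT \to CATG$, and the later $\ell=1$ pass joins
$ATCA \to ACAT$, giving $p = 8$ — here equal to the exact optimum computed
by `brute_force_scs()`, though the greedy strategy carries no such
guarantee in general (the classical bound for this family of heuristics is
a constant-factor approximation). A trace that stops after using only the
longest overlaps would report $p = 9$ on the same input; our builder runs
all $m-1$ passes, so it never misses short joins, and the verification
suite asserts $p \le 9$ rather than a specific trace.

`verify_pseudogenome()` re-checks every invariant above plus verbatim read
recovery, returning diagnostics instead of raising, and is run on every
build in the test suite.

## The index

### Suffix array with read-relative entries

A suffix array over $PG$ is built by prefix doubling over integer symbol
ranks (any correct construction is equivalent; the brute-force sort of all
suffixes exists independently in the tests as the oracle). Each entry
stores not the text position but the *furthest read* covering the suffix
start — the placement with the largest offset $\le$ the position, ties
between co-located duplicate reads resolved toward the later placement —
and the offset inside that read. This makes read identification free: a
hit at text position $t$ with furthest placement $\pi$ contributes nothing
if $t - j_\pi + k > m$ (the pattern would cross every covering read's
end, since earlier placements only increase the in-read offset), and
otherwise yields $(u_\pi, t - j_\pi)$ followed by a backward scan over the
placement array while the pattern still fits.

### Sparsification

With sparsity $s \in \{2..6\}$ only entries at text positions divisible by
$s$ are kept (position 0 always sampled; $s$ need not divide $p$), each
carrying the $s-1$ symbols preceding it — padded with a `-` sentinel that
matches nothing before the text start — so that a query of length
$k \ge s$ is resolved by $s$ binary searches: for shift
$r \in \{0..\min(s,k)-1\}$, search for $f[r..k)$ and accept a sampled
entry when its cached trailing $r$ symbols equal $f[0..r)$; the occurrence
starts $r$ positions before the sample. Each occurrence is found under
exactly one shift, so no deduplication is needed. Queries shorter than $s$
are rejected (this is the price of sparsification). In memory the cached
symbols are kept as plain characters and packed only in the serialized
container; packing density is deliberately decoupled from $s$, which ties
the two only as a cache-layout micro-optimization.

### Lookup table

For a prefix length $l$, the LUT maps each of the $\sigma^l$ possible
prefixes to its half-open interval of suffix-array ranks; binary searches
for patterns of length $\ge l$ are confined to (and seeded by) the
interval of the pattern's $l$-prefix. Suffixes shorter than $l$ belong to
no interval and can never match such patterns. The classical choice
$l = 11$ gives $4^{11}$ or $5^{11}$ cells — both under 50M — appropriate
for gigabase-scale pseudogenomes; the default here adapts instead,
$l = \min(11, \lfloor \log_\sigma \max(p, 2) \rfloor)$, so that small
indexes do not allocate millions of empty cells. `lut_entry_count()`
exposes the sizing arithmetic and `--lut-len` overrides the default.
$N$-containing prefixes are ordinary LUT citizens when $\sigma = 5$.

### Repetitive-read flags

At build time each read is flagged if some 11-mer (configurable,
`flag_len`) occurs in it at least twice, occurrences may overlap. For a
query of length $k \ge 11$, an unflagged read that contains the pattern
contains it exactly once — any double occurrence of $f$ with $|f| \ge 11$
would repeat an 11-mer — so the single-occurrence queries Q5–Q7 skip
per-read counting for unflagged reads. When `flag_len` exceeds $m$ no such
mer exists and all flags are false (the fast path simply never fires).

### Count caches

For $k$ up to `cache_max_k` (desk default 8; 0 disables) the three counting
answers Q2/Q4/Q6 are precomputed for all $4^k$ ACGT k-mers. For
`cache_max_k` $< k \le$ `cache_ext_k` a single narrow array (1- or 2-byte
cells) stores the common value only when $Q2 = Q4 = Q6$ and it is below
the cell's sentinel ($2^8{-}1$ or $2^{16}{-}1$); the sentinel — an
otherwise unused value — signals "not cached" and the live path answers.
This exploits the empirical near-coincidence of the three counts for long
k-mers. Caches cover the 4-letter alphabet only; any query containing `N`,
exceeding the bounds, or hitting a sentinel takes the live path. The test
suite asserts cell-by-cell agreement with the live computation.

### Fixed-k mode

When all queries share one length $k$, every suffix whose in-read offset
satisfies $\text{offset} + k > m$ for its furthest placement is pruned
(containment in the furthest read is equivalent to containment in any),
and the LUT is rebuilt. Every surviving entry of a pattern's range then
contributes at least one occurrence, so the range width never exceeds
$|Q3|$ — asserted over randomized patterns in the tests. Pruning is
restricted to dense indexes; combining it with sparsification is out of
scope here.

## Query semantics and normalization

The normative definitions are: Q3 = all $(\text{read}, \text{position})$
occurrences, Q4 = $|Q3|$, Q1 = distinct reads of Q3, Q2 = $|Q1|$, Q5 =
reads with *exactly one* occurrence, Q6 = $|Q5|$, Q7 = the single
occurrence per Q5 read. Output order is normalized for testability —
Q1/Q5 ascending by read ID, Q3/Q7 ascending by (read ID, position) — since
the definitions themselves impose none. Positional queries
$(\text{read ID}, \text{start}, k)$ resolve to the read substring and are
indistinguishable downstream. Patterns match exactly; `N` matches only
`N`, and a pattern containing `N` against a 4-letter index is answered
empty rather than rejected.

The classical mutable-flag device (occurrence and single-occurrence bits
in the placement records, unwound via a stack after each query, which
forces single-threaded querying) is an optimization for pointer-level
implementations, not semantics; this implementation aggregates per query
in local state, so the placement flags are false before and after every
call — `placement_flags()` exposes them and the suite asserts the hygiene
invariant after $10^4$ mixed queries. The repetitive-read fast path *is*
taken for real where valid.

## Synthetic data

`simulate_reads()` emulates shotgun sampling: a uniformly random reference
of length $G$, $q$ reads as verbatim windows at uniform starts, i.i.d.
substitutions at rate $e$ (to a different base) and i.i.d. `N` replacement
at rate `n_rate`; identical spec and seed give identical output. It does
*not* model realistic error profiles (position-dependent quality,
indels), paired ends, or coverage biases — so passing tests demonstrate
correctness of the index machinery on uniformly overlapping data, not
performance claims about real libraries. The compression property tested
(error-free reads at $5\times$ coverage, $G = 1000$, $q = 100$, $m = 50$:
$p < qm$ for every seed) is a structural sanity check, since overlaps are
guaranteed to exist at that coverage.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in the public
  interface; read IDs are 0-based input order.
* `N`'s collation rank (between `G` and `T`) follows ASCII; no convention
  is canonical, and the choice affects suffix order but no query answer.
* Duplicate reads chain with placement delta 0; the furthest-read tie at
  equal offsets goes to the later placement so the backward scan
  enumerates all co-located duplicates.
* A single read is its own pseudogenome; a read of length $< 2$ is
  rejected.
* Packing pads the final unit with `A` and keeps the true length; all six
  density variants (2–4 per byte, 4–6 per 2-byte unit) are validated
  against $\sigma^d$ fitting the unit.
* The `.pgsa` container stores only non-derivable sections (header, packed
  text, placements, read-relative entries, LUT, caches); sparse cached
  symbols and text positions are reconstructed on load, which is why a
  load–save round trip is byte-identical.

## Problem sizes in the verification suite

The suite runs 100 randomized read sets ($q \le 60$, $m \le 24$, both
alphabets) through dense, sparse ($s$ drawn from 2–6), fixed-$k$ and
cache-enabled indexes with exhaustive query lengths against the
brute-force oracle; suffix order is checked against a full sort on a
pseudogenome of ~$10^4$ symbols; flag hygiene after $10^4$ mixed queries;
and exact-SCS lower bounds by permutation enumeration for $q \le 6$. These
sizes keep the whole suite around two minutes on one core while covering
every code path; the structures themselves have no small-size
assumptions.

## Known limitations

* Reverse-complemented placement is not attempted: the merge considers
  reads as given. Folding in reverse complements shortens pseudogenomes
  only moderately while complicating every query path, and is future work.
* Exact SCS is only feasible for $q \le 7$ (factorial enumeration); the
  builder's output is a heuristic upper bound.
* Construction is in-memory and single-threaded; disk-based suffix
  sorting and concurrent querying are out of scope.
* Approximate matching (mismatches, IUPAC ambiguity beyond `N`) is not
  supported; the index is exact-match by design.
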