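# pgsuffix

Indexing collections of fixed-length DNA sequencing reads for k-mer
counting and locating queries, in main memory.

## The problem

Many read-level analyses — error correction, variant screening, RNA-seq
support profiles, reference-free clustering — need to ask, for an arbitrary
pattern `f` drawn from the reads, the seven classical read-indexing
queries:

| query | answer |
|-------|--------|
| Q1 | in which reads does `f` occur? |
| Q2 | in how many reads does `f` occur? |
| Q3 | at which (read, position) pairs does `f` occur? |
| Q4 | how many occurrences of `f` are there in total? |
| Q5 | in which reads does `f` occur exactly once? |
| Q6 | in how many reads does `f` occur exactly once? |
| Q7 | where does `f` occur, in the reads where it occurs exactly once? |

A generalized suffix array over all reads answers these but wastes space on
the massive redundancy of shotgun data. `pgsuffix` instead:

1. merges the `q` reads (each of length `m`) greedily along maximal
   suffix-prefix overlaps into one short superstring, the **pseudogenome**
   `PG[0..p)` — a heuristic for the NP-hard shortest common superstring
   problem — together with a placement array recording where each read
   lands;
2. builds a **suffix array** over `PG` whose entries are stored in
   read-relative coordinates (the *furthest* read covering each suffix
   start, plus the offset inside it), so a binary-search hit immediately
   names reads; a backward scan over the placement array then enumerates
   every other read containing the same occurrence;
3. optionally **sparsifies** the array (keep every `s`-th text position,
   `s ≤ 6`, caching the `s−1` preceding symbols so queries of length
   `k ≥ s` are answered by searching the `s` shifted pattern suffixes), adds
   a prefix **lookup table** seeding the binary search, per-read
   **repetitive flags** (true when some 11-mer repeats within the read, so
   an unflagged read provably contains a long pattern at most once), and
   precomputed **count caches** for short ACGT k-mers;
4. supports a **fixed-k mode** that prunes every suffix whose `k`-prefix
   crosses a read boundary, after which a pattern's suffix-array range is
   never wider than its occurrence list.

Queries may be given as a DNA string or positionally as
`(read ID, start, length)`. All read IDs and positions are **0-based**.
Patterns match exactly; `N` matches only `N`.

## Worked example

The three reads `ACAT`, `CATG`, `ATCA` admit the superstring `ACATCATG` of
length 8 (`ACAT`∘`ATCA` with overlap 2, then ∘`CATG` with overlap 3); a
purely greedy longest-overlap-first merge is not guaranteed to find it, but
does here via the late length-1 join:

```r
library(pgsuffix)
rs  <- read_set(c("ACAT", "CATG", "ATCA"))
pg  <- build_pseudogenome(rs)
pg
#> pseudogenome: p = 8 symbols from q = 3 reads of length m = 4 (p/(q*m) = 0.667)
cat(placement_dump(pg), sep = "\n")   # offset  read-ID  sequence
#> 0  2  ATCA
#> 3  0  ACAT
#> 4  1  CATG
brute_force_scs(rs$reads)$length      # exact optimum, by enumeration
#> [1] 8

idx <- build_index(rs)
str(pg_query(idx, "CAT", "all"))
#> List of 7
#>  $ Q1: int [1:2] 0 1          # CAT occurs in reads 0 and 1
#>  $ Q2: int 2
#>  $ Q3:'data.frame': 2 obs.    # at (read 0, pos 1) and (read 1, pos 0)
#>  $ Q4: int 2
#>  $ Q5: int [1:2] 0 1          # once in each
#>  $ Q6: int 2
#>  $ Q7: same positions as Q3
```

`naive_answer()` computes the same seven answers by a sliding-window scan
of every read and is the oracle the test suite compares every index
configuration against; `verify_pseudogenome()` checks the structural
invariants of a build.

## Command line

A thin `pgsuffix` script (installed under `exec/`) wraps the package:

```sh
pgsuffix generate reads.fastq --ref-length 10000 --n-reads 1000 --read-length 100 --seed 1
pgsuffix build reads.fastq reads.pgsa --sparsity 2 --cache-max-k 8
pgsuffix query reads.pgsa queries.txt --which Q2     # lines: "S ACGT..." or "P id start k"
pgsuffix verify reads.pgsa reads.fastq --samples 100 --seed 7
pgsuffix stats reads.pgsa
```

Indexes are stored in a versioned little-endian binary container
(`.pgsa`): header, packed pseudogenome (2-bit or ~3-symbols-per-byte
packing by alphabet), placements, read-relative suffix array entries,
lookup table, count caches.

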