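test_that("suffix order matches a hand-enumerated example and brute force", {
  pg1 <- toy_trace_pg()
  sa <- build_suffix_array(pg1)
  expect_equal(sa$pos, c(8L, 0L, 5L, 2L, 7L, 1L, 4L, 6L, 3L))
  expect_equal(sa$pos, brute_sa(pg1))

  tiny <- structure(list(pg = "AC", p = 2L, m = 2L, q = 1L, sigma = 4L,
                         offsets = 0L, orig_ids = 0L), class = "pseudogenome")
  expect_equal(build_suffix_array(tiny)$pos, c(0L, 1L))

  set.seed(21)
  for (i in 1:10) {
    rs <- random_read_set(sample(10:60, 1), sample(5:20, 1),
                          n_rate = ifelse(i %% 3 == 0, 0.05, 0))
    pg <- build_pseudogenome(rs)
    expect_equal(build_suffix_array(pg)$pos, brute_sa(pg))
  }
})

test_that("read-relative coordinates pick the furthest covering placement", {
  pg <- toy_trace_pg()
  sa <- build_suffix_array(pg)
  # PG position 2 is covered by ACAT@0 and CATG@1; furthest start is 1
  i <- which(sa$pos == 2L)
  expect_equal(sa$place[i], 2L)     # placement index (1-based internally)
  expect_equal(sa$off[i], 1L)
  i0 <- which(sa$pos == 0L)
  expect_equal(sa$place[i0], 1L)
  expect_equal(sa$off[i0], 0L)
  # the mapping inverts exactly and is a bijection onto PG positions
  expect_setequal(pg$offsets[sa$place] + sa$off, 0:(pg$p - 1L))

  # co-located duplicates: the later placement wins the tie
  dup <- build_pseudogenome(read_set(c("ACGT", "ACGT")))
  sad <- build_suffix_array(dup)
  expect_true(all(sad$place == 2L))
})

test_that("sparsification samples positions divisible by s and caches context", {
  pg <- toy_trace_pg()
  dense <- build_suffix_array(pg)
  sp <- sparsify(dense, 2L, pg)
  expect_setequal(sp$pos, c(0L, 2L, 4L, 6L, 8L))   # ceil(9/2) = 5 samples
  expect_equal(length(sp$pos), 5L)
  # cached preceding symbol of sampled position 4 is PG[3] = "T"
  expect_equal(sp$cached_prefix[sp$pos == 4L], "T")
  expect_equal(sp$cached_prefix[sp$pos == 0L], "-")  # before text start
  # order preserved among survivors
  expect_equal(sp$pos, dense$pos[dense$pos %% 2L == 0L])

  expect_error(sparsify(dense, 7L, pg), "between 2 and 6")
  expect_error(sparsify(dense, 1L, pg), "between 2 and 6")
})

test_that("the lookup table reproduces unrestricted binary search intervals", {
  pg <- toy_trace_pg()
  sa <- build_suffix_array(pg)
  lut <- build_lookup_table(sa, pg, l = 1L)
  # prefix 'A' covers SA ranks 1..4 (suffix starts 8, 0, 5, 2)
  expect_equal(lut$first[1L], 1L)
  expect_equal(lut$count[1L], 4L)
  # absent prefix has a zero-width interval
  pgA <- structure(list(pg = "AAAA", p = 4L, m = 4L, q = 1L, sigma = 4L,
                        offsets = 0L, orig_ids = 0L), class = "pseudogenome")
  lutA <- build_lookup_table(build_suffix_array(pgA), pgA, l = 1L)
  expect_equal(lutA$count, c(4L, 0L, 0L, 0L))

  expect_equal(lut_entry_count(5, 11), 5^11)

  # LUT-seeded search equals full binary search for every present pattern
  set.seed(22)
  rs <- random_read_set(30, 12)
  for (l in 1:4) {
    idx_l <- build_index(rs, lut_len = l, cache_max_k = 0)
    idx_f <- build_index(rs, lut_len = 1L, cache_max_k = 0)
    for (k in l:12) for (r in 1:3) {
      f <- present_pattern(rs, k)
      expect_identical(locate_range(idx_l, f)$range,
                       locate_range(idx_f, f)$range)
    }
  }
})

test_that("repetitive flags equal the brute-force substring count", {
  expect_true(compute_repetitive_flags(read_set("ACACAC"), l = 2L))
  expect_false(compute_repetitive_flags(read_set("ACGT"), l = 2L))
  expect_equal(compute_repetitive_flags(read_set(c("AAAA", "ACGT")), l = 5L),
               c(FALSE, FALSE))  # no 5-mer exists in 4-symbol reads
  set.seed(23)
  rs <- random_read_set(40, 15)
  for (l in c(2L, 3L, 5L, 11L)) {
    want <- vapply(rs$reads, function(r) {
      w <- substring(r, 1:(nchar(r) - l + 1L), l:nchar(r))
      any(table(w) >= 2L)
    }, logical(1), USE.NAMES = FALSE)
    expect_equal(compute_repetitive_flags(rs, l), want)
  }
})

test_that("fixed-k pruning keeps exactly the in-read suffixes", {
  pg <- toy_trace_pg()
  rs <- toy_reads()
  idx <- build_index(rs, cache_max_k = 0)
  # on the hand-laid trace layout, k = 4 keeps only read starts {0, 1, 5}
  sa <- build_suffix_array(pg)
  keep <- sa$off + 4L <= 4L
  expect_setequal(sa$pos[keep], c(0L, 1L, 5L))

  idx4 <- prune_fixed_k(idx, 4L)
  expect_equal(idx4$fixed_k, 4L)
  expect_true(all(idx4$sa$off + 4L <= idx4$pg$m))
  # k = 1 prunes nothing: every position lies inside a read
  idx1 <- prune_fixed_k(build_index(rs, cache_max_k = 0), 1L)
  expect_equal(length(idx1$sa$pos), idx1$pg$p)

  expect_error(prune_fixed_k(build_index(rs, cache_max_k = 0), 5L),
               "query longer than read")
  expect_error(build_index(rs, sparsity = 2, fixed_k = 2),
               "requires a dense")
})

test_that("count caches agree with the live query path, with sentinel fallback", {
  set.seed(24)
  rs <- random_read_set(30, 12)
  cache <- precompute_count_cache(rs, base_max_k = 4L, ext_max_k = 6L,
                                  ext_cell_bytes = 2L)
  idx <- build_index(rs, cache_max_k = 0)     # live path only
  for (k in 1:6) for (r in 1:10) {
    f <- if (r <= 6) present_pattern(rs, k) else random_pattern(k)
    live <- naive_answer(rs, f, "all")
    for (w in c("Q2", "Q4", "Q6")) {
      v <- cache_lookup(cache, f, w)
      if (!is.null(v)) expect_equal(v, live[[w]])
      else expect_gt(k, 4L)   # NULL only in the extended range (sentinel)
    }
  }
  # absent k-mer: all three cached counts are zero
  expect_equal(cache_lookup(cache, "GG", "Q4"),
               naive_answer(rs, "GG", "Q4"))

  # a k-mer occurring twice in one read and nowhere else: Q2=1, Q4=2, Q6=0,
  # so the extended cache must store the sentinel and defer to the live path
  rs2 <- read_set(c("AAGGCAAGGC", "TTTTTTTTTT"))
  c2 <- precompute_count_cache(rs2, base_max_k = 2L, ext_max_k = 5L)
  expect_equal(naive_answer(rs2, "AAGGC", "Q4"), 2L)
  expect_equal(naive_answer(rs2, "AAGGC", "Q6"), 0L)
  expect_null(cache_lookup(c2, "AAGGC", "Q2"))
  # while a genuinely unique 5-mer is served from the extended cache
  expect_equal(cache_lookup(c2, "AGGCA", "Q4"), 1L)
})
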