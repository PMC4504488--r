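test_that("the worked three-read example answers all seven queries", {
  rs <- toy_reads()
  idx <- build_index(rs, cache_max_k = 2)
  res <- pg_query(idx, "CAT", "all")
  expect_equal(res$Q1, c(0L, 1L))
  expect_equal(res$Q2, 2L)
  expect_equal(res$Q3, data.frame(read_id = c(0L, 1L), pos = c(1L, 0L)))
  expect_equal(res$Q4, 2L)
  expect_equal(res$Q5, c(0L, 1L))
  expect_equal(res$Q6, 2L)
  expect_equal(res$Q7, res$Q3)

  # single-symbol pattern: A at ACAT{0,2}, CATG{1}, ATCA{0,3}
  a <- pg_query(idx, "A", "all")
  expect_equal(a$Q4, 5L)
  expect_equal(a$Q2, 3L)
  expect_equal(a$Q5, 1L)
  expect_equal(a$Q6, 1L)
  expect_equal(a$Q7, data.frame(read_id = 1L, pos = 1L))

  # absent pattern: everything empty or zero
  g <- pg_query(idx, "GGGG", "all")
  expect_length(g$Q1, 0L)
  expect_equal(g$Q2, 0L)
  expect_equal(nrow(g$Q3), 0L)
  expect_equal(g$Q4, 0L)
  expect_equal(g$Q6, 0L)

  # full-read pattern locates through the backward placement scan
  expect_equal(pg_query(idx, "ATCA", "Q3"),
               data.frame(read_id = 2L, pos = 0L))
})

test_that("malformed patterns are rejected", {
  idx <- build_index(toy_reads(), cache_max_k = 0)
  expect_error(pg_query(idx, "", "Q1"), "empty query")
  expect_error(pg_query(idx, "ACGTA", "Q1"), "query longer than read")
  expect_error(pg_query(idx, "ACXT", "Q1"), "invalid symbol")
})

test_that("positional queries resolve to their substring and answer identically", {
  rs <- toy_reads()
  idx <- build_index(rs)
  expect_equal(resolve_positional(rs, 1, 0, 3), "CAT")
  expect_equal(resolve_positional(rs, 0, 3, 1), "T")
  expect_equal(resolve_positional(idx, 1, 0, 3), "CAT")  # index form
  expect_error(resolve_positional(rs, 0, 2, 3), "outside the read")
  expect_error(resolve_positional(rs, 3, 0, 2), "out of range")

  set.seed(31)
  rs2 <- random_read_set(25, 14)
  idx2 <- build_index(rs2, cache_max_k = 0)
  for (i in 1:20) {
    k <- sample(1:14, 1)
    rid <- sample(rs2$q, 1) - 1L
    st <- sample(14 - k + 1, 1) - 1L
    f <- resolve_positional(rs2, rid, st, k)
    res <- pg_query(idx2, f, "all")
    expect_identical(res, pg_query(idx2, f, "all"))
    expect_true(rid %in% res$Q1)   # a positional query finds its own read
    expect_identical(res, naive_answer(rs2, f, "all"))
  }
})

test_that("dense, sparse, fixed-k and cached answers all equal the oracle", {
  set.seed(32)
  for (it in 1:12) {
    m <- sample(6:20, 1)
    rs <- random_read_set(sample(5:40, 1), m,
                          n_rate = ifelse(it %% 4 == 0, 0.05, 0))
    idx <- build_index(rs, cache_max_k = 4)
    s <- sample(2:min(6, m - 1), 1)
    idxs <- build_index(rs, sparsity = s, cache_max_k = 0)
    fk <- sample(1:m, 1)
    idxf <- build_index(rs, fixed_k = fk, cache_max_k = 0)
    for (k in 1:m) for (r in 1:2) {
      f <- if (r == 1) present_pattern(rs, k)
           else random_pattern(k, c("A", "C", "G", "T", "N"))
      want <- naive_answer(rs, f, "all")
      expect_equal(pg_query(idx, f, "all"), want)
      for (w in c("Q2", "Q4", "Q6"))     # exercises the cache for k <= 4
        expect_equal(pg_query(idx, f, w), want[[w]])
      if (k >= s) expect_equal(pg_query(idxs, f, "all"), want)
      if (k == fk) {
        expect_equal(pg_query(idxf, f, "all"), want)
        rng <- locate_range(idxf, f)$range
        expect_lte(rng[2L] - rng[1L], want$Q4)  # range width <= |Q3|
      }
    }
    expect_error(pg_query(idxs, substr(rs$reads[1], 1, s - 1), "Q1"),
                 "shorter than sparsity")
    if (fk < m)
      expect_error(pg_query(idxf, substr(rs$reads[1], 1, fk + 1), "Q1"),
                   "fixed k")
  }
})

test_that("cross-query relations hold on randomized inputs", {
  set.seed(33)
  rs <- random_read_set(40, 16, n_rate = 0.03)
  idx <- build_index(rs, sparsity = 2, cache_max_k = 0)
  for (i in 1:40) {
    k <- sample(2:16, 1)
    f <- if (i %% 2) present_pattern(rs, k) else random_pattern(k)
    r <- pg_query(idx, f, "all")
    expect_equal(r$Q2, length(r$Q1))
    expect_equal(r$Q4, nrow(r$Q3))
    expect_equal(r$Q6, length(r$Q5))
    expect_equal(r$Q6, nrow(r$Q7))
    expect_lte(r$Q6, r$Q2)
    expect_lte(r$Q2, r$Q4)
    expect_true(all(r$Q5 %in% r$Q1))
    if (nrow(r$Q7))
      expect_true(all(do.call(paste, r$Q7) %in% do.call(paste, r$Q3)))
  }
})

test_that("placement flags stay false through arbitrary query sequences", {
  set.seed(34)
  rs <- random_read_set(30, 12)
  idx <- build_index(rs, cache_max_k = 3)
  for (i in 1:50) pg_query(idx, present_pattern(rs, sample(1:12, 1)),
                           sample(c("all", "Q1", "Q5", "Q7"), 1))
  fl <- placement_flags(idx)
  expect_false(any(fl$occurrence))
  expect_false(any(fl$single_occurrence))
  expect_equal(fl$repetitive, idx$rep_flags[fl$read_id + 1L])
})

test_that("the repetitive-read fast path is consistent with counting", {
  # reads where an 11-mer repeats vs. reads where none does
  rep_read <- paste0(strrep("ACGTACGTACG", 2), "TT")  # 24 bp, repeated 11-mer
  uni_read <- paste0("ACGTTGCAATCGGATCCTAGGCAA")
  rs <- read_set(c(rep_read, uni_read))
  idx <- build_index(rs, cache_max_k = 0)
  expect_true(idx$rep_flags[1L])
  expect_false(idx$rep_flags[2L])
  f <- substr(rep_read, 1, 11)           # occurs twice in the flagged read
  expect_equal(pg_query(idx, f, "all"), naive_answer(rs, f, "all"))
  expect_equal(pg_query(idx, f, "Q6"), 0L)
  f2 <- substr(uni_read, 3, 13)
  expect_equal(pg_query(idx, f2, "Q6"), naive_answer(rs, f2, "Q6"))
})
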