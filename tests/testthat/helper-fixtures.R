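# Shared fixtures, all built in code.

# the three-read worked example used throughout
toy_reads <- function() read_set(c("ACAT", "CATG", "ATCA"))

# a hand-laid pseudogenome over the same three reads, ACATGATCA with
# placements ACAT@0, CATG@1, ATCA@5 -- a valid (non-minimal) layout whose
# suffix structure is small enough to enumerate by hand
toy_trace_pg <- function() {
  structure(
    list(pg = "ACATGATCA", p = 9L, m = 4L, q = 3L, sigma = 4L,
         offsets = c(0L, 1L, 5L), orig_ids = c(0L, 1L, 2L)),
    class = "pseudogenome")
}

# brute-force suffix sort oracle: 0-based start positions in lexicographic
# order (radix = byte order, i.e. A < C < G < N < T)
brute_sa <- function(pg) {
  order(substring(pg$pg, 1:pg$p, pg$p), method = "radix") - 1L
}

random_read_set <- function(q, m, error_rate = 0.02, n_rate = 0,
                            ref_length = NULL) {
  if (is.null(ref_length)) ref_length <- max(3L * m, q * m %/% 4L)
  simulate_reads(ref_length, q, m, error_rate, n_rate)$reads
}

random_pattern <- function(k, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, k, replace = TRUE), collapse = "")
}

# pattern sampled from a read (guaranteed present)
present_pattern <- function(rs, k) {
  rid <- sample.int(rs$q, 1L)
  st <- sample.int(rs$m - k + 1L, 1L)
  substr(rs$reads[rid], st, st + k - 1L)
}

write_toy_fasta <- function(path = tempfile(fileext = ".fa")) {
  writeLines(c(">r1", "ACAT", ">r2", "CATG", ">r3", "ATCA"), path)
  path
}
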