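Package: pgsuffix
Title: Pseudogenome Suffix Array Indexing of Fixed-Length Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a compact superstring (a "pseudogenome") of a collection
    of equal-length DNA sequencing reads by greedy suffix-prefix overlap
    merging, indexes it with an optionally sparse suffix array carrying
    read-relative coordinates, and answers the seven classical read-indexing
    k-mer queries (which reads contain a pattern, how many, at which
    positions, and the single-occurrence variants) for arbitrary query
    lengths. Includes a brute-force reference oracle, an exact shortest
    common superstring solver for small instances, a synthetic read
    generator, a versioned binary index container and a command-line
    interface for building, querying and verifying indexes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
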