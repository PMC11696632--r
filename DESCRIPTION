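Package: moveindex
Title: Move Structure Full-Text Index for Repetitive DNA References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and queries the move structure, a run-length compressed,
    table-based full-text index over the Burrows-Wheeler Transform (BWT) of
    DNA reference collections such as pangenomes. The index supports
    LF-mapping with fast-forwards, optional run splitting for a constant
    fast-forward bound, threshold-based repositioning (scan and stored-pointer
    modes), pseudo-matching length (PML) computation, and backward-search
    count queries. Brute-force oracles (suffix array, LCP, rank, matching
    statistics, naive counting) are included for verification, together with
    a deterministic synthetic-pangenome and read simulator and a command-line
    interface for building, querying and inspecting indexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
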