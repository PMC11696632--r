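# Shared fixtures: all test inputs are generated in code, seeded.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random single-record text of total length n (incl. sentinel), forward only
random_index_text <- function(n, seed) {
  build_text(stats::setNames(random_dna(n - 1L, seed), "g"), include_rc = FALSE)
}

# independent suffix-array oracle: direct sort of all suffixes
# (radix = C-locale byte order, so '$' < 'A' < 'C' < 'G' < 'T')
naive_sa <- function(t) {
  n <- t$n
  order(substring(t$text, 1:n, n), method = "radix") - 1L
}

# direct pairwise longest-common-prefix of adjacent sorted suffixes
naive_lcp <- function(t, sa) {
  n <- t$n
  out <- integer(n)
  for (k in 2:n) {
    a <- t$codes[(sa[k - 1] + 1):n]
    b <- t$codes[(sa[k] + 1):n]
    L <- min(length(a), length(b))
    d <- which(a[seq_len(L)] != b[seq_len(L)])
    out[k] <- if (length(d) == 0) L else d[1] - 1L
  }
  out
}

# sweep every BWT offset: lf_move must equal the precomputed LF vector and
# land inside a valid row; returns -1 on success, else the first bad offset
sweep_lf <- function(M, lf) {
  for (i in seq_len(M$nrows)) {
    p <- M$p[i]
    for (o in seq_len(M$l[i]) - 1L) {
      j <- p + o
      res <- lf_move(M, list(run = i, offset = j))
      if (res$offset != lf[j + 1L]) return(j)
      if (M$p[res$run] > res$offset ||
          res$offset >= M$p[res$run] + M$l[res$run]) return(j)
    }
  }
  -1L
}

# default 4-copy pangenome used by the query suites
pangenome_text <- function(seed = 101L, copies = 4L, base_len = 1000L,
                           mut_rate = 0.001) {
  build_text(simulate_pangenome(base_len, copies, mut_rate, 0, seed),
             include_rc = TRUE)
}

# mixed read set: error-free, 5%-error, and off-target random reads
mixed_reads <- function(t, n_total = 999L, read_len = 150L, seed = 7L) {
  n1 <- ceiling(n_total / 3)
  n2 <- floor(n_total / 3)
  n3 <- n_total - n1 - n2
  c(sample_reads(t, n1, read_len, 0, seed),
    sample_reads(t, n2, read_len, 0.05, seed + 1L),
    random_reads(n3, read_len, seed + 2L))
}
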