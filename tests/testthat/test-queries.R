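# Query algorithms: PMLs, backward-search counting, batching.

test_that("PMLs extend by case 1 on a fully matching read", {
  idx <- build_index(c(x = "ACG"), include_rc = FALSE, keep_scaffold = TRUE)
  res <- compute_pmls(idx, "ACG", start = 0L)
  expect_equal(res$pmls, c(3L, 2L, 1L))
  expect_equal(res$counters$case2_events, 0L)
  expect_equal(res$counters$lf_steps, 3L)
  expect_equal(pml_oracle(attr(idx, "scaffold"), "ACG"), c(3L, 2L, 1L))
})

test_that("characters outside the index alphabet record 0 and hold position", {
  idx <- build_index(c(x = "ACGT"), include_rc = FALSE)
  res <- compute_pmls(idx, "NNNN")
  expect_equal(res$pmls, rep(0L, 4))
  expect_equal(res$counters$lf_steps, 0L)
  # absent-from-BWT characters behave the same way ('T' absent here)
  idx2 <- build_index(c(x = "ACG"), include_rc = FALSE)
  expect_equal(compute_pmls(idx2, "TT")$pmls, c(0L, 0L))
  # empty read
  expect_equal(compute_pmls(idx, "")$pmls, integer(0))
})

test_that("querying an index without thresholds is a configuration error", {
  t <- build_text(c(x = "ACG"), include_rc = FALSE)
  bwt <- bwt_from_sa(t, build_suffix_array(t))
  M <- build_move_table(run_length_encode(bwt), bwt, build_rank_oracle(bwt))
  expect_error(compute_pmls(M, "ACG"), "configuration error")
  expect_error(batch_query(M, c(r = "ACG")), "configuration error")
})

test_that("PMLs are dominated by matching statistics", {
  t <- pangenome_text(seed = 211L, copies = 2L, base_len = 400L)
  idx <- build_index(t)
  reads <- c(sample_reads(t, 20, 100, 0, 212L),
             sample_reads(t, 20, 100, 0.05, 213L),
             random_reads(10, 100, 214L))
  for (i in seq_along(reads)) {
    pml <- compute_pmls(idx, reads[[i]])$pmls
    ms <- matching_statistics_oracle(t, reads[[i]])
    expect_true(all(pml <= ms))
  }
  # error-free reads are exact substrings: MS[i] = L - i + 1 exactly
  for (rd in sample_reads(t, 5, 100, 0, 215L)) {
    expect_equal(matching_statistics_oracle(t, rd), 100:1)
  }
})

test_that("init_range delimits the F-column block of a character", {
  idx <- build_index(c(x = "ACG"), include_rc = FALSE)
  rng <- init_range(idx, "A")
  expect_false(rng$empty)
  expect_equal(rng$top$offset, 1L)
  expect_equal(rng$bottom$offset, 1L)
  expect_true(init_range(idx, "T")$empty)

  t <- random_index_text(300, 221)
  idx2 <- build_index(t)
  for (c in c("A", "C", "G", "T")) {
    rng2 <- init_range(idx2, c)
    width <- rng2$bottom$offset - rng2$top$offset + 1L
    expect_equal(width, sum(t$codes == match(c, MOVE_ALPHABET)))
  }
})

test_that("backward extension narrows the range to the oracle's count", {
  idx <- build_index(c(x = "AAAA"), include_rc = FALSE)
  rng <- init_range(idx, "A")
  rng2 <- backward_extend(idx, rng, "A")
  expect_false(rng2$empty)
  expect_equal(rng2$bottom$offset - rng2$top$offset + 1L, 3L)
  # extending by a character absent within the range empties it
  expect_true(backward_extend(idx, rng2, "C")$empty)
  expect_error(backward_extend(idx, backward_extend(idx, rng2, "C"), "A"),
               "contract violation")

  t <- random_index_text(500, 231)
  idx2 <- build_index(t)
  set.seed(232)
  for (rep in 1:60) {
    len <- sample(2:8, 1)
    st <- sample(t$n - len, 1)
    P <- substr(t$text, st, st + len - 1L)
    chars <- strsplit(P, "")[[1]]
    rng3 <- init_range(idx2, chars[len])
    for (i in rev(seq_len(len - 1L))) rng3 <- backward_extend(idx2, rng3, chars[i])
    width <- if (rng3$empty) 0L else rng3$bottom$offset - rng3$top$offset + 1L
    expect_equal(width, count_oracle(t, P))
  }
})

test_that("count queries equal the naive oracle, including absent patterns", {
  idx <- build_index(c(x = "ACG"), include_rc = FALSE)
  expect_equal(count_occurrences(idx, "ACG"), 1L)
  expect_equal(count_occurrences(idx, "CA"), 0L)
  expect_equal(count_occurrences(build_index(c(x = "AAAA"), include_rc = FALSE), "AA"), 3L)
  expect_equal(count_occurrences(idx, "ANG"), 0L)  # non-alphabet char

  t <- random_index_text(600, 241)
  idx2 <- build_index(t)
  set.seed(242)
  for (rep in 1:100) {
    len <- sample(1:10, 1)
    st <- sample(t$n - len, 1)
    P <- substr(t$text, st, st + len - 1L)
    expect_equal(count_occurrences(idx2, P), count_oracle(t, P))
  }
  for (rep in 1:30) {
    P <- random_dna(14, 242 + rep)
    expect_equal(count_occurrences(idx2, P), count_oracle(t, P))
  }
})

test_that("PMLs agree across default mode, constant mode and the plain BWT", {
  t <- pangenome_text(seed = 251L, copies = 3L, base_len = 500L)
  scaf <- build_scaffold(t)
  Md <- build_index(t, mode = "default")
  Mc <- build_index(t, mode = "constant", d = 4L)
  reads <- mixed_reads(t, n_total = 60L, read_len = 120L, seed = 252L)
  for (rd in reads) {
    ref <- pml_oracle(scaf, rd)
    expect_identical(compute_pmls(Md, rd)$pmls, ref)
    expect_identical(compute_pmls(Mc, rd)$pmls, ref)
  }
})

test_that("batched querying is independent of batch size and preserves order", {
  t <- pangenome_text(seed = 261L, copies = 2L, base_len = 400L)
  idx <- build_index(t)
  reads <- mixed_reads(t, n_total = 45L, read_len = 90L, seed = 262L)
  r1 <- batch_query(idx, reads, batch_size = 1L)
  seqres <- lapply(seq_along(reads), function(i) {
    compute_pmls(idx, reads[[i]], name = names(reads)[i])
  })
  expect_identical(lapply(r1, `[[`, "pmls"), lapply(seqres, `[[`, "pmls"))
  for (B in c(2L, 16L, 32L)) {
    expect_identical(batch_query(idx, reads, batch_size = B), r1)
  }
  expect_identical(vapply(r1, `[[`, "", "name"), names(reads))
})

test_that("constant-mode query counters respect the balancing bounds", {
  t <- pangenome_text(seed = 271L, copies = 3L, base_len = 400L)
  d <- 4L
  idx <- build_index(t, mode = "constant", d = d)
  reads <- sample_reads(t, 10, 100, 0.05, 272L)
  for (rd in reads) {
    res <- compute_pmls(idx, rd)
    # repositioning costs exactly 1 per case-2 event in pointer mode
    expect_equal(res$counters$reposition_scans, res$counters$case2_events)
    # fast-forwards are < 2d per LF step
    expect_lt(res$counters$fast_forwards, 2L * d * max(res$counters$lf_steps, 1L))
  }
})
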