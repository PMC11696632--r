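# Indexed text construction and the brute-force BWT machinery.

test_that("build_text appends the sentinel and handles reverse complements", {
  t <- build_text(c(x = "ACG"), include_rc = FALSE)
  expect_equal(t$text, "ACG$")
  expect_equal(t$n, 4L)
  expect_false(t$includes_rc)

  t2 <- build_text(c(x = "ACG"), include_rc = TRUE)
  expect_equal(t2$text, "ACGCGT$")
  expect_equal(t2$n, 7L)
  expect_equal(t2$record_boundaries$name, c("x", "x_rc"))
  expect_equal(t2$record_boundaries$start, c(0L, 3L))
  expect_equal(t2$record_boundaries$end, c(3L, 6L))
})

test_that("alphabet policy strips or rejects non-ACGT characters", {
  expect_warning(t <- build_text(c(x = "ACNG"), include_rc = FALSE,
                                 alphabet_policy = "strip"),
                 "stripped 1 non-ACGT")
  expect_equal(t$text, "ACG$")

  expect_error(build_text(c(x = "ACNG"), include_rc = FALSE,
                          alphabet_policy = "reject"),
               "record 'x'.*'N' at offset 2")
  expect_error(build_text(character(0)), "no input records")
  expect_warning(
    expect_error(build_text(c(ok = "ACGT", bad = "NNN"), include_rc = FALSE),
                 "empty after applying alphabet policy"))
  # lowercase input is normalised
  expect_equal(build_text(c(x = "acgt"), include_rc = FALSE)$text, "ACGT$")
})

test_that("suffix array matches direct suffix sorting", {
  expect_equal(build_suffix_array(build_text(c(x = "ACG"), include_rc = FALSE)),
               c(3L, 0L, 1L, 2L))
  expect_equal(build_suffix_array(build_text(c(x = "AAAA"), include_rc = FALSE)),
               c(4L, 3L, 2L, 1L, 0L))
  for (seed in 1:10) {
    t <- random_index_text(sample(20:200, 1), seed)
    sa <- build_suffix_array(t)
    expect_setequal(sa, 0:(t$n - 1L))
    expect_identical(sa, naive_sa(t))
  }
})

test_that("BWT follows the preceding-character rule and counts runs", {
  t <- build_text(c(x = "ACG"), include_rc = FALSE)
  b <- bwt_from_sa(t, build_suffix_array(t))
  expect_equal(b$bwt, "G$AC")
  expect_equal(b$r, 4L)

  t2 <- build_text(c(x = "AAAA"), include_rc = FALSE)
  b2 <- bwt_from_sa(t2, build_suffix_array(t2))
  expect_equal(b2$bwt, "AAAA$")
  expect_equal(b2$r, 2L)

  # the BWT is an anagram of the text
  t3 <- random_index_text(150, 3)
  b3 <- bwt_from_sa(t3, build_suffix_array(t3))
  expect_identical(sort(b3$codes), sort(t3$codes))
  expect_lte(b3$r, t3$n)
})

test_that("LCP array equals direct pairwise comparison", {
  t <- build_text(c(x = "AAAA"), include_rc = FALSE)
  sa <- build_suffix_array(t)
  expect_equal(lcp_from_sa(t, sa), c(0L, 0L, 1L, 2L, 3L))

  t2 <- build_text(c(x = "ACG"), include_rc = FALSE)
  expect_equal(lcp_from_sa(t2, build_suffix_array(t2)), rep(0L, 4))

  for (seed in 11:14) {
    t3 <- random_index_text(sample(30:150, 1), seed)
    sa3 <- build_suffix_array(t3)
    lcp <- lcp_from_sa(t3, sa3)
    expect_identical(lcp, naive_lcp(t3, sa3))
    expect_true(all(lcp >= 0 & lcp <= t3$n))
  }
})

test_that("lf_oracle is the rank-based LF and a bijection", {
  t <- build_text(c(x = "ACG"), include_rc = FALSE)
  b <- bwt_from_sa(t, build_suffix_array(t))
  rk <- build_rank_oracle(b)
  expect_equal(sapply(0:3, function(j) lf_oracle(b, rk, j)), c(3L, 0L, 1L, 2L))
  expect_error(lf_oracle(b, rk, 4L), "out of range")

  t2 <- random_index_text(400, 21)
  b2 <- bwt_from_sa(t2, build_suffix_array(t2))
  rk2 <- build_rank_oracle(b2)
  lf <- sapply(0:(t2$n - 1L), function(j) lf_oracle(b2, rk2, j))
  expect_setequal(lf, 0:(t2$n - 1L))  # bijection

  # iterating LF from the sentinel's BWM row visits every offset once and
  # reads the text right-to-left
  j <- 0L
  seen <- integer(0)
  chars <- character(t2$n)
  for (k in seq_len(t2$n)) {
    seen <- c(seen, j)
    chars[k] <- substr(b2$bwt, j + 1L, j + 1L)
    j <- lf[j + 1L]
  }
  expect_setequal(seen, 0:(t2$n - 1L))
  # the cycle reads T right-to-left, ending on the sentinel
  expect_equal(chars[t2$n], "$")
  expect_equal(paste(rev(chars[-t2$n]), collapse = ""),
               substr(t2$text, 1, t2$n - 1L))
})

test_that("matching statistics oracle obeys its definition and monotonicity", {
  t <- build_text(c(x = "ACG"), include_rc = FALSE)
  expect_equal(matching_statistics_oracle(t, "ACG"), c(3L, 2L, 1L))
  expect_equal(matching_statistics_oracle(t, "T"), 0L)

  for (seed in 31:34) {
    t2 <- random_index_text(200, seed)
    P <- random_dna(40, seed + 100)
    ms <- matching_statistics_oracle(t2, P)
    m <- length(ms)
    expect_true(all(ms[-m] <= ms[-1] + 1L))  # MS[i] <= MS[i+1] + 1
    # spot-check the definition directly
    body <- substr(t2$text, 1, t2$n - 1)
    for (i in c(1L, m %/% 2L, m)) {
      if (ms[i] > 0) {
        expect_true(grepl(substr(P, i, i + ms[i] - 1L), body, fixed = TRUE))
      }
      if (i + ms[i] <= m) {
        expect_false(grepl(substr(P, i, i + ms[i]), body, fixed = TRUE))
      }
    }
  }
})

test_that("count oracle counts overlapping occurrences, sentinel excluded", {
  expect_equal(count_oracle(build_text(c(x = "AAAA"), include_rc = FALSE), "AA"), 3L)
  t <- build_text(c(x = "ACG"), include_rc = FALSE)
  expect_equal(count_oracle(t, "CA"), 0L)
  expect_equal(count_oracle(t, "ACG"), 1L)  # whole text occurs once
  expect_equal(count_oracle(t, "ACG$"), 0L)  # sentinel never matches
})

test_that("BWT inverts to the text via iterated LF on random texts", {
  for (seed in 41:50) {
    t <- random_index_text(sample(50:500, 1), seed)
    b <- bwt_from_sa(t, build_suffix_array(t))
    rk <- build_rank_oracle(b)
    j <- 0L
    chars <- character(t$n)
    for (k in seq_len(t$n)) {
      chars[k] <- substr(b$bwt, j + 1L, j + 1L)
      j <- rk$lf[j + 1L]
    }
    expect_equal(paste(rev(chars[-t$n]), collapse = ""),
                 substr(t$text, 1, t$n - 1L))
  }
})
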