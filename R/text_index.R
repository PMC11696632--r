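# Construction of the indexed text and the ground-truth (brute-force) BWT
# machinery: suffix array, BWT, LCP array, rank/C-array, LF, matching
# statistics and naive occurrence counting. These structures are both the
# build inputs for the move table and the oracles every query is verified
# against.

#' Build the indexed text
#'
#' Concatenates one or more named DNA records into a single text, optionally
#' followed by the reverse complement of every record (in record order), and
#' terminated by the sentinel `$`. Offsets are 0-based and half-open
#' throughout the package.
#'
#' @param records Named character vector (or list) of DNA sequences, e.g. as
#'   returned by [read_fasta()].
#' @param include_rc Append the reverse complement of each record so that both
#'   strands are indexed (default `TRUE`); reverse-complement blocks are named
#'   `<record>_rc`.
#' @param alphabet_policy What to do with characters outside `A`,`C`,`G`,`T`:
#'   `"strip"` removes them with a warning, `"reject"` raises an error naming
#'   the record and 0-based offset of the first offender.
#' @return An object of class `index_text`: a list with `text` (the full
#'   string including the sentinel), `codes` (integer codes 1..5), `n` (length
#'   including sentinel), `record_boundaries` (data frame of 0-based half-open
#'   `(name, start, end)` intervals) and `includes_rc`.
#' @examples
#' t <- build_text(c(x = "ACG"), include_rc = FALSE)
#' t$text  # "ACG$"
#' @export
build_text <- function(records, include_rc = TRUE,
                       alphabet_policy = c("strip", "reject")) {
  policy <- match.arg(alphabet_policy)
  if (is.list(records)) records <- unlist(records)
  if (length(records) == 0L) stop("build error: no input records")
  seqs <- toupper(as.character(records))
  nm <- names(records)
  if (is.null(nm)) nm <- sprintf("record_%d", seq_along(seqs))

  for (i in seq_along(seqs)) {
    codes <- .code_map[utf8ToInt(seqs[i])]
    bad <- is.na(codes) | codes == 1L  # sentinel may not occur in records
    if (any(bad)) {
      if (policy == "reject") {
        off <- which(bad)[1L]
        stop(sprintf(
          "validation error: record '%s' contains non-ACGT character '%s' at offset %d",
          nm[i], substr(seqs[i], off, off), off - 1L))
      }
      warning(sprintf(
        "record '%s': stripped %d non-ACGT character(s)", nm[i], sum(bad)),
        call. = FALSE)
      seqs[i] <- .decode_codes(codes[!bad])
    }
  }
  if (any(!nzchar(seqs))) {
    stop(sprintf("build error: record '%s' is empty after applying alphabet policy",
                 nm[which(!nzchar(seqs))[1L]]))
  }

  parts <- seqs
  part_names <- nm
  if (include_rc) {
    parts <- c(seqs, revcomp(seqs))
    part_names <- c(nm, paste0(nm, "_rc"))
  }
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens
  text <- paste0(paste(parts, collapse = ""), "$")
  structure(list(
    text = text,
    codes = .code_map[utf8ToInt(text)],
    n = nchar(text),
    record_boundaries = data.frame(name = part_names, start = starts,
                                   end = ends, stringsAsFactors = FALSE),
    includes_rc = include_rc
  ), class = "index_text")
}

#' @export
print.index_text <- function(x, ...) {
  cat(sprintf("index_text: n = %d (incl. sentinel), %d block(s), includes_rc = %s\n",
              x$n, nrow(x$record_boundaries), x$includes_rc))
  invisible(x)
}

#' Read a (multi-)FASTA file
#'
#' Records may be line-wrapped; the record name is the header up to the first
#' whitespace. Sequences are returned verbatim (case and ambiguity codes
#' preserved) so that [build_text()]'s alphabet policy can act on them.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), nms)
}

#' Read query reads from FASTA or FASTQ
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (default; decided from the file extension, falling
#'   back to the first character), `"fasta"` or `"fastq"`. Qualities are
#'   ignored.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fasta"
    } else {
      first <- substr(readLines(path, n = 1L), 1L, 1L)
      if (identical(first, "@")) "fastq" else "fasta"
    }
  }
  x <- Biostrings::readBStringSet(path, format = format)
  nms <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), nms)
}

#' Build the suffix array
#'
#' Prefix-doubling construction (O(n log n) rounds of radix `order()`): with a
#' unique smallest sentinel, sorted rotations coincide with sorted suffixes.
#'
#' @param t An `index_text`, or a plain character string over `$ACGT`.
#' @return Integer vector `sa` with 0-based start offsets: `sa[k]` (1-based
#'   `k`) is the start of the k-th lexicographically smallest suffix.
#' @examples
#' build_suffix_array(build_text(c(x = "ACG"), include_rc = FALSE))  # 3 0 1 2
#' @export
build_suffix_array <- function(t) {
  codes <- if (inherits(t, "index_text")) t$codes else .encode_chars(t)
  n <- length(codes)
  if (n == 1L) return(0L)
  rk <- codes
  k <- 1L
  repeat {
    key2 <- if (k < n) c(rk[(k + 1L):n], rep.int(0L, k)) else rep.int(0L, n)
    ord <- order(rk, key2, method = "radix")
    r1 <- rk[ord]
    r2 <- key2[ord]
    newrk <- cumsum(c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n]))
    rk[ord] <- newrk
    if (newrk[[n]] == n) break
    k <- k + k
  }
  sa <- integer(n)
  sa[rk] <- seq_len(n) - 1L
  sa
}

#' Burrows-Wheeler Transform from a suffix array
#'
#' `bwt[k] = text[sa[k] - 1]`, wrapping to the final character (the sentinel's
#' predecessor is `text[n-1]`) when `sa[k] = 0`.
#'
#' @param t An `index_text`.
#' @param sa Suffix array built from `t`.
#' @return Object of class `bwt_string`: list with `bwt` (string), `codes`
#'   (integer codes), `r` (number of maximal runs) and `n`.
#' @export
bwt_from_sa <- function(t, sa) {
  n <- t$n
  prev <- ifelse(sa == 0L, n, sa)  # 1-based index of preceding character
  codes <- t$codes[prev]
  r <- 1L + sum(codes[-1L] != codes[-n])
  structure(list(bwt = .decode_codes(codes), codes = codes, r = r, n = n),
            class = "bwt_string")
}

#' @export
print.bwt_string <- function(x, ...) {
  cat(sprintf("bwt_string: n = %d, r = %d runs (n/r = %.2f)\n",
              x$n, x$r, x$n / x$r))
  invisible(x)
}

#' LCP array (Kasai's algorithm)
#'
#' `lcp[k]` (0-based `k`, returned as `lcp[k+1]`) is the length of the longest
#' common prefix of the suffixes at sorted ranks `k-1` and `k`; `lcp[0] = 0`.
#'
#' @param t An `index_text`.
#' @param sa Suffix array built from `t`.
#' @return Integer vector of length `n`.
#' @export
lcp_from_sa <- function(t, sa) {
  n <- t$n
  codes <- t$codes
  rank <- integer(n)
  rank[sa + 1L] <- seq_len(n) - 1L  # rank of suffix starting at each offset
  lcp <- integer(n)
  h <- 0L
  for (i0 in 0:(n - 1L)) {
    rk <- rank[i0 + 1L]
    if (rk > 0L) {
      j0 <- sa[rk]  # predecessor suffix in sorted order (0-based start)
      while (i0 + h < n && j0 + h < n &&
             codes[i0 + h + 1L] == codes[j0 + h + 1L]) {
        h <- h + 1L
      }
      lcp[rk + 1L] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Rank/C-array structure over a BWT
#'
#' Standard FM machinery: `C[c]` counts characters strictly smaller than `c`
#' in the text, and a cumulative occurrence matrix answers
#' `rank(c, j) = #occurrences of c in bwt[0..j)`.
#'
#' @param bwt A `bwt_string`.
#' @return Object of class `rank_oracle`: list with `C` (named by alphabet
#'   character), `counts`, the inclusive occurrence matrix `occ` (n x 5) and a
#'   precomputed full `lf` vector (`lf[j+1] = LF[j]`, 0-based offsets).
#' @export
build_rank_oracle <- function(bwt) {
  codes <- bwt$codes
  n <- bwt$n
  occ <- vapply(1:5, function(k) cumsum(codes == k), integer(n))
  counts <- occ[n, ]
  Cvec <- c(0L, cumsum(counts)[-5L])
  lf <- Cvec[codes] + occ[cbind(seq_len(n), codes)] - 1L
  structure(list(C = stats::setNames(Cvec, MOVE_ALPHABET),
                 counts = stats::setNames(counts, MOVE_ALPHABET),
                 occ = occ, lf = lf, n = n),
            class = "rank_oracle")
}

#' Ground-truth LF-mapping
#'
#' `LF[j] = C[bwt[j]] + rank(bwt[j], j)`: the F-column position of the text
#' character sitting at BWT offset `j`. This is the reference against which
#' [lf_move()] is validated.
#'
#' @param bwt A `bwt_string`.
#' @param ranks A `rank_oracle` built from `bwt`.
#' @param j 0-based BWT offset.
#' @return 0-based BWT offset `LF[j]`.
#' @export
lf_oracle <- function(bwt, ranks, j) {
  if (j < 0L || j >= bwt$n) stop("index error: offset out of range")
  k <- bwt$codes[j + 1L]
  rank_before <- if (j == 0L) 0L else ranks$occ[j, k]
  unname(ranks$C[k] + rank_before)
}

#' Matching statistics by exhaustive search
#'
#' `MS[i]` is the length of the longest prefix of `P[i..m]` occurring in the
#' indexed text (sentinel excluded from matches). Computed by direct substring
#' search, exploiting `MS[i+1] >= MS[i] - 1` to resume extension.
#'
#' @param t An `index_text`.
#' @param P Pattern string (query alphabet; characters absent from the text
#'   simply contribute 0).
#' @return Integer vector of length `nchar(P)`.
#' @export
matching_statistics_oracle <- function(t, P) {
  stopifnot(nchar(P) > 0L)
  body <- substr(t$text, 1L, t$n - 1L)
  P <- toupper(P)
  m <- nchar(P)
  ms <- integer(m)
  prev <- 0L
  for (i in seq_len(m)) {
    len <- max(prev - 1L, 0L)
    while (i + len <= m && grepl(substr(P, i, i + len), body, fixed = TRUE)) {
      len <- len + 1L
    }
    ms[i] <- len
    prev <- len
  }
  ms
}

#' Naive occurrence count
#'
#' Sliding-window count of (possibly overlapping) occurrences of `P` in the
#' text, sentinel excluded.
#'
#' @param t An `index_text`.
#' @param P Pattern string.
#' @return Integer count.
#' @export
count_oracle <- function(t, P) {
  stopifnot(nchar(P) > 0L)
  pc <- .encode_chars(toupper(P))
  if (anyNA(pc)) return(0L)
  body <- t$codes[-t$n]
  m <- length(pc)
  nb <- length(body)
  if (m > nb) return(0L)
  hits <- which(body[seq_len(nb - m + 1L)] == pc[1L])
  if (m > 1L) {
    for (k in 2:m) {
      hits <- hits[body[hits + k - 1L] == pc[k]]
      if (length(hits) == 0L) break
    }
  }
  length(hits)
}

#' Build all plain-BWT structures for a text
#'
#' Convenience bundle of the ground-truth structures (suffix array, BWT, LCP,
#' rank oracle, per-character occurrence lists) used by the oracles, by the
#' reference PML implementation, and as inputs to the move-table build.
#'
#' @param t An `index_text`.
#' @return Object of class `bwt_scaffold`: list with `t`, `sa`, `bwt`, `lcp`,
#'   `ranks` and `occ_by_code` (0-based occurrence offsets per alphabet code).
#' @export
build_scaffold <- function(t) {
  sa <- build_suffix_array(t)
  bwt <- bwt_from_sa(t, sa)
  lcp <- lcp_from_sa(t, sa)
  ranks <- build_rank_oracle(bwt)
  occ_by_code <- lapply(1:5, function(k) which(bwt$codes == k) - 1L)
  structure(list(t = t, sa = sa, bwt = bwt, lcp = lcp, ranks = ranks,
                 occ_by_code = occ_by_code),
            class = "bwt_scaffold")
}

# min of lcp over sorted-suffix ranks (a, b]; equals LCP of suffixes ranked a and b
.lcp_range_min <- function(lcp, a, b) min(lcp[(a + 2L):(b + 1L)])
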