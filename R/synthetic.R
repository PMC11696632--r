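# Deterministic generators for pangenome-like references and reads. A
# pangenome is emulated as one random base genome plus mutated copies;
# repetition across copies is what drives BWT run-length compression (r << n),
# the trend the r-growth experiment reproduces in miniature.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(s, mut_rate, indel_rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  subs <- which(stats::runif(n) < mut_rate)
  for (i in subs) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    if (length(ev) > 0L) {
      out <- vector("list", n)
      for (i in seq_len(n)) out[[i]] <- ch[i]
      for (i in ev) {
        if (stats::runif(1L) < 0.5) {
          out[[i]] <- character(0)                       # deletion
        } else {
          out[[i]] <- c(sample(c("A", "C", "G", "T"), 1L), ch[i])  # insertion
        }
      }
      ch <- unlist(out)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a synthetic pangenome
#'
#' One uniform-random base genome plus `n_copies - 1` independently mutated
#' copies. Mutations are substitutions to a uniformly random different base at
#' rate `mut_rate` per base, plus optional single-base indel events at
#' `indel_rate` (deletion or random-base insertion, equally likely). Fully
#' deterministic given the seed.
#'
#' @param base_len Base genome length in bp (default 1000).
#' @param n_copies Total number of genome copies (`>= 1`).
#' @param mut_rate Per-base substitution probability (default 0.001).
#' @param indel_rate Per-base indel event probability (default 0).
#' @param seed Integer seed.
#' @return Named character vector of `n_copies` records (`genome_01`, ...).
#' @export
simulate_pangenome <- function(base_len = 1000L, n_copies = 1L,
                               mut_rate = 0.001, indel_rate = 0,
                               seed = 1L) {
  stopifnot(base_len >= 1L, n_copies >= 1L,
            mut_rate >= 0, mut_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  .with_seed(seed, {
    base <- .random_bases(base_len)
    recs <- character(n_copies)
    recs[1L] <- base
    if (n_copies > 1L) {
      for (i in 2:n_copies) recs[i] <- .mutate_seq(base, mut_rate, indel_rate)
    }
    stats::setNames(recs, sprintf("genome_%02d", seq_len(n_copies)))
  })
}

#' Sample reads from an indexed text
#'
#' Reads are drawn uniformly (weighted by eligible start positions) from the
#' record blocks of the text -- both strands when the text includes reverse
#' complements -- and never span the sentinel or a block boundary. With
#' `error_rate = 0` every read is an exact substring of the indexed text.
#'
#' @param t An `index_text`.
#' @param n_reads Number of reads.
#' @param read_len Read length (must fit in the longest record block).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Integer seed.
#' @return Named character vector of reads (`read_000001`, ...).
#' @export
sample_reads <- function(t, n_reads, read_len = 150L, error_rate = 0,
                         seed = 1L) {
  rec <- t$record_boundaries
  lens <- rec$end - rec$start
  ok <- lens >= read_len
  if (!any(ok)) stop("read_len exceeds every record block")
  rec <- rec[ok, , drop = FALSE]
  weights <- (rec$end - rec$start) - read_len + 1L
  .with_seed(seed, {
    blocks <- sample.int(nrow(rec), n_reads, replace = TRUE,
                         prob = weights / sum(weights))
    starts <- rec$start[blocks] +
      floor(stats::runif(n_reads) * weights[blocks])
    reads <- substring(t$text, starts + 1L, starts + read_len)
    if (error_rate > 0) {
      for (i in seq_len(n_reads)) {
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        err <- which(stats::runif(read_len) < error_rate)
        for (e in err) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1L)
        reads[i] <- paste(ch, collapse = "")
      }
    }
    stats::setNames(reads, sprintf("read_%06d", seq_len(n_reads)))
  })
}

#' Random reads unrelated to any reference
#'
#' Uniform-random ACGT sequences; used as off-target queries.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length.
#' @param seed Integer seed.
#' @return Named character vector.
#' @export
random_reads <- function(n_reads, read_len = 150L, seed = 1L) {
  .with_seed(seed, {
    stats::setNames(
      vapply(seq_len(n_reads), function(i) .random_bases(read_len), ""),
      sprintf("rand_%06d", seq_len(n_reads)))
  })
}

#' Distinct canonical k-mers of a set of records
#'
#' A canonical k-mer is the lexicographic minimum of a k-mer and its reverse
#' complement, so both strands collapse to one representative.
#'
#' @param records Character vector of DNA sequences.
#' @param k k-mer length (default 31).
#' @return Integer count of distinct canonical k-mers.
#' @export
count_canonical_kmers <- function(records, k = 31L) {
  kmers <- unlist(lapply(records, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }))
  if (length(kmers) == 0L) return(0L)
  kmers <- unique(kmers)
  length(unique(pmin(kmers, revcomp(kmers))))
}

#' Run-length compression growth across pangenome copies
#'
#' Builds the index text for increasing numbers of copies of the same
#' synthetic pangenome (copies are nested: the k-copy set is a prefix of the
#' largest) and reports text length `n`, BWT run count `r`, the compression
#' ratio `n/r`, and the number of distinct canonical k-mers. With low mutation
#' rates `n` grows linearly in the number of copies while `r` grows far more
#' slowly, so `n/r` increases.
#'
#' @param copies_list Increasing integer vector of copy numbers.
#' @param mut_rate Per-base substitution rate (default 0.001).
#' @param seed Integer seed.
#' @param base_len Base genome length (default 1000).
#' @param k Canonical k-mer length (default 31).
#' @param include_rc Index both strands (default `TRUE`).
#' @return Data frame with columns `copies`, `n`, `r`, `n_over_r`,
#'   `distinct_kmers`.
#' @export
r_growth_experiment <- function(copies_list, mut_rate = 0.001, seed = 1L,
                                base_len = 1000L, k = 31L, include_rc = TRUE) {
  stopifnot(all(diff(copies_list) > 0))
  recs <- simulate_pangenome(base_len, max(copies_list), mut_rate, 0, seed)
  rows <- lapply(copies_list, function(kc) {
    t <- build_text(recs[seq_len(kc)], include_rc = include_rc)
    bwt <- bwt_from_sa(t, build_suffix_array(t))
    data.frame(copies = kc, n = t$n, r = bwt$r, n_over_r = t$n / bwt$r,
               distinct_kmers = count_canonical_kmers(recs[seq_len(kc)], k))
  })
  do.call(rbind, rows)
}

#' Write sequences as FASTA or FASTQ
#'
#' FASTA output goes through [Biostrings::writeXStringSet()]; FASTQ records
#' are written directly with constant quality `I`.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_seqs <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    nms <- names(seqs)
    if (is.null(nms)) nms <- sprintf("read_%d", seq_along(seqs))
    lines <- as.vector(rbind(paste0("@", nms), unname(seqs), "+",
                             strrep("I", nchar(seqs))))
    writeLines(lines, path)
  }
  invisible(path)
}
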