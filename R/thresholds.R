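# Thresholds and repositioning. On a query/BWT mismatch ("case 2") the cursor
# must move to the nearest BWT offset above (jup) or below (jdn) carrying the
# query character; the side with the longer LCP between its sorted suffix and
# the suffix at the current offset is chosen. Per run and character, a single
# threshold offset t encodes that decision: offsets j < t go up, j >= t go
# down. t is the (last) minimum of the LCP array between the two surrounding
# occurrences of the character, so the threshold decision reproduces the
# longest-LCP choice exactly (ties resolved towards jup).

#' Compute per-run, per-character thresholds
#'
#' For each row and each alphabet character `c` different from the row
#' character, the threshold is placed at the offset of the (last) minimum LCP
#' value in the sorted-suffix range between the previous and next occurrence
#' of `c`, clamped into the row: `t = p` encodes "always down" (no `c` above),
#' `t = p + l` encodes "always up" (no `c` below). Rows of character `c`
#' itself hold `NA`. A character absent from the whole BWT yields an all-`NA`
#' column (no repositioning target exists).
#'
#' @param M A `move_table` (after any splitting).
#' @param bwt The underlying `bwt_string`.
#' @param lcp LCP array from [lcp_from_sa()].
#' @return Integer matrix `nrows x 5` (columns named by [MOVE_ALPHABET]),
#'   class `threshold_set`.
#' @export
compute_thresholds <- function(M, bwt, lcp) {
  nr <- M$nrows
  thr <- matrix(NA_integer_, nrow = nr, ncol = 5L,
                dimnames = list(NULL, MOVE_ALPHABET))
  for (k in 1:5) {
    occ <- which(bwt$codes == k) - 1L  # 0-based offsets of character k
    if (length(occ) == 0L) next
    nseg <- length(occ) - 1L
    seg_t <- integer(nseg)
    if (nseg > 0L) {
      for (s in seq_len(nseg)) {
        a <- occ[s]
        b <- occ[s + 1L]
        seg <- lcp[(a + 2L):(b + 1L)]           # lcp indices a+1 .. b
        idx <- length(seg) - which.min(rev(seg)) + 1L  # last argmin
        seg_t[s] <- a + idx
      }
    }
    rows <- which(M$code != k)
    p <- M$p[rows]
    l <- M$l[rows]
    s <- findInterval(p, occ)  # occurrences of k above each row
    t <- integer(length(rows))
    t[s == 0L] <- p[s == 0L]                       # nothing above: always down
    t[s == length(occ)] <- p[s == length(occ)] + l[s == length(occ)]  # always up
    mid <- s > 0L & s < length(occ)
    t[mid] <- pmin(pmax(seg_t[s[mid]], p[mid]), p[mid] + l[mid])
    thr[rows, k] <- t
  }
  class(thr) <- c("threshold_set", class(thr))
  thr
}

#' Ground-truth repositioning choice
#'
#' Finds `jup` (greatest offset `< j` with `BWT[jup] = c`) and `jdn`
#' (smallest offset `> j`), computes the LCP between the sorted suffix at
#' each candidate and the one at `j`, and returns the candidate with the
#' longer LCP (tie broken towards `jup`).
#'
#' @param bwt A `bwt_string`.
#' @param lcp LCP array of the same text.
#' @param j 0-based BWT offset.
#' @param c Target character.
#' @return `NULL` if `c` does not occur in the BWT; otherwise a list with
#'   `offset` (the chosen candidate), `side` (`"up"`/`"down"`), `jup`, `jdn`,
#'   `lcp_up`, `lcp_dn` (`NA` where one-sided).
#' @export
reposition_oracle <- function(bwt, lcp, j, c) {
  k <- .char_to_code(c)
  occ <- which(bwt$codes == k) - 1L
  if (length(occ) == 0L) return(NULL)
  iu <- findInterval(j - 1L, occ)
  jup <- if (iu >= 1L) occ[iu] else NA_integer_
  id <- findInterval(j, occ) + 1L
  jdn <- if (id <= length(occ)) occ[id] else NA_integer_
  lcp_up <- if (!is.na(jup)) .lcp_range_min(lcp, jup, j) else NA_integer_
  lcp_dn <- if (!is.na(jdn)) .lcp_range_min(lcp, j, jdn) else NA_integer_
  side <- if (is.na(jdn) || (!is.na(jup) && lcp_up >= lcp_dn)) "up" else "down"
  list(offset = if (side == "up") jup else jdn,
       side = side, jup = jup, jdn = jdn, lcp_up = lcp_up, lcp_dn = lcp_dn)
}

# shared threshold decision: TRUE = go up
.reposition_dir_up <- function(M, pos, k) {
  thr <- M$thresholds
  if (is.null(thr)) stop("configuration error: thresholds have not been computed")
  t <- thr[pos$run, k]
  if (is.na(t)) stop("internal error: missing threshold for present character")
  pos$offset < t
}

.reposition_scan_code <- function(M, pos, k, counters = NULL) {
  if (M$code[pos$run] == k) {
    stop("contract violation: position already carries the target character")
  }
  if (M$counts[k] == 0L) return(NULL)  # no-match signal
  up <- .reposition_dir_up(M, pos, k)
  code <- M$code
  i <- pos$run
  if (up) {
    i2 <- i - 1L
    while (i2 >= 1L && code[i2] != k) i2 <- i2 - 1L
    if (i2 < 1L) stop("internal error: threshold points up but no run above")
    off <- M$p[i2] + M$l[i2] - 1L  # last offset of the run (nearest to pos)
  } else {
    i2 <- i + 1L
    while (i2 <= M$nrows && code[i2] != k) i2 <- i2 + 1L
    if (i2 > M$nrows) stop("internal error: threshold points down but no run below")
    off <- M$p[i2]                 # first offset of the run
  }
  if (!is.null(counters)) {
    counters$reposition_scans <- counters$reposition_scans + abs(i2 - i)
  }
  list(run = i2, offset = off)
}

#' Reposition by scanning (default mode)
#'
#' Chooses the direction from the row's threshold for `c`, scans consecutive
#' rows in that direction to the nearest run of `c`, and lands on that run's
#' last offset (upward) or first offset (downward). The repositioning-scan
#' counter is incremented by the number of rows traversed.
#'
#' @param M A `move_table` with thresholds computed.
#' @param pos Current position (its BWT character must differ from `c`).
#' @param c Target character.
#' @param counters Optional counters environment.
#' @return New position, or `NULL` if `c` is absent from the BWT.
#' @export
reposition_scan <- function(M, pos, c, counters = NULL) {
  .reposition_scan_code(M, pos, .char_to_code(c), counters)
}

#' Build repositioning pointers (constant mode)
#'
#' For every row and character, the index of the nearest run above and below
#' carrying that character (for the DNA alphabet this is the paper's six
#' pointers per row: three foreign characters, two directions; the sentinel
#' column is kept for completeness). `NA` where no such run exists or for the
#' row's own character.
#'
#' @param M A `move_table` (after any splitting).
#' @return List of two `nrows x 5` integer matrices, `up` and `dn`, class
#'   `reposition_pointers`.
#' @export
build_reposition_pointers <- function(M) {
  nr <- M$nrows
  up <- matrix(NA_integer_, nr, 5L, dimnames = list(NULL, MOVE_ALPHABET))
  dn <- matrix(NA_integer_, nr, 5L, dimnames = list(NULL, MOVE_ALPHABET))
  for (k in 1:5) {
    rows_k <- which(M$code == k)
    if (length(rows_k) == 0L) next
    iu <- findInterval(seq_len(nr) - 1L, rows_k)
    up[, k] <- ifelse(iu >= 1L, rows_k[pmax(iu, 1L)], NA_integer_)
    id <- findInterval(seq_len(nr), rows_k) + 1L
    dn[, k] <- ifelse(id <= length(rows_k),
                      rows_k[pmin(id, length(rows_k))], NA_integer_)
    own <- M$code == k
    up[own, k] <- NA_integer_
    dn[own, k] <- NA_integer_
  }
  structure(list(up = up, dn = dn), class = "reposition_pointers")
}

.reposition_pointer_code <- function(M, pos, k, ptrs, counters = NULL) {
  if (M$code[pos$run] == k) {
    stop("contract violation: position already carries the target character")
  }
  if (M$counts[k] == 0L) return(NULL)
  up <- .reposition_dir_up(M, pos, k)
  i2 <- unname(if (up) ptrs$up[pos$run, k] else ptrs$dn[pos$run, k])
  if (is.na(i2)) stop("internal error: threshold direction has no pointer target")
  off <- if (up) M$p[i2] + M$l[i2] - 1L else M$p[i2]
  if (!is.null(counters)) {
    counters$reposition_scans <- counters$reposition_scans + 1L
  }
  list(run = i2, offset = off)
}

#' Reposition via stored pointers (constant mode)
#'
#' Same contract as [reposition_scan()] but resolved with a single pointer
#' dereference; the repositioning counter is incremented by exactly 1.
#'
#' @inheritParams reposition_scan
#' @param ptrs Pointers from [build_reposition_pointers()] (defaults to the
#'   ones stored on the table).
#' @return New position, or `NULL` if `c` is absent from the BWT.
#' @export
reposition_pointer <- function(M, pos, c, ptrs = NULL, counters = NULL) {
  if (is.null(ptrs)) {
    if (is.null(M$ptr_up)) {
      stop("configuration error: repositioning pointers have not been built")
    }
    ptrs <- list(up = M$ptr_up, dn = M$ptr_dn)
  }
  .reposition_pointer_code(M, pos, .char_to_code(c), ptrs, counters)
}
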