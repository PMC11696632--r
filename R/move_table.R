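# The move structure: one table row per BWT run, holding the run character c,
# length l, head offset p, the LF of the head (pi) and the index of the run
# containing pi (xi). LF at any offset is pi + (j - p) followed by a
# "fast-forward" scan over consecutive rows to land in the right run.

#' Operation counters
#'
#' Mutable counter set threaded through queries: LF steps, fast-forwards
#' (rows advanced past `xi`), repositioning scans (rows traversed on a
#' mismatch; exactly 1 per event in pointer mode) and case-2 events.
#'
#' @return An environment with fields `lf_steps`, `fast_forwards`,
#'   `reposition_scans`, `case2_events`, all 0.
#' @export
new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$lf_steps <- 0L
  e$fast_forwards <- 0L
  e$reposition_scans <- 0L
  e$case2_events <- 0L
  e
}

#' @rdname new_counters
#' @param counters A counters environment.
#' @export
counters_snapshot <- function(counters) {
  list(lf_steps = counters$lf_steps,
       fast_forwards = counters$fast_forwards,
       reposition_scans = counters$reposition_scans,
       case2_events = counters$case2_events)
}

#' Run-length encode a BWT
#'
#' @param bwt A `bwt_string`.
#' @return Data frame with one row per maximal run, in left-to-right order:
#'   `c` (run character), `l` (length), `p` (0-based head offset).
#' @examples
#' t <- build_text(c(x = "ACG"), include_rc = FALSE)
#' run_length_encode(bwt_from_sa(t, build_suffix_array(t)))
#' @export
run_length_encode <- function(bwt) {
  stopifnot(bwt$n > 0L)
  enc <- rle(bwt$codes)
  l <- as.integer(enc$lengths)
  data.frame(c = MOVE_ALPHABET[enc$values], l = l,
             p = cumsum(l) - l, stringsAsFactors = FALSE)
}

#' Build the move table
#'
#' For each run: `pi = LF[p]` (via the rank oracle) and `xi` = index of the
#' run whose interval contains `pi`.
#'
#' @param runs Data frame from [run_length_encode()].
#' @param bwt The `bwt_string` the runs were computed from.
#' @param ranks A `rank_oracle` built from `bwt`.
#' @return Object of class `move_table`; row columns are stored as plain
#'   integer/character vectors (`c`, `code`, `l`, `p`, `pi`, `xi`) together
#'   with `n`, `nrows`, `r_original`, `mode` (`"default"` until
#'   [split_runs()] is applied), per-character counts and C-array, and slots
#'   for thresholds and repositioning pointers (populated by
#'   [compute_thresholds()] / [build_reposition_pointers()]).
#' @export
build_move_table <- function(runs, bwt, ranks) {
  code <- match(runs$c, MOVE_ALPHABET)
  if (anyNA(code) || sum(runs$l) != bwt$n ||
      !identical(rep.int(code, runs$l), bwt$codes)) {
    stop("build error: runs are inconsistent with the BWT")
  }
  p <- as.integer(runs$p)
  pi <- ranks$lf[p + 1L]
  xi <- findInterval(pi, p)
  counts <- ranks$counts
  structure(list(
    c = runs$c, code = code, l = as.integer(runs$l), p = p,
    pi = pi, xi = xi,
    nrows = nrow(runs), n = bwt$n, r_original = nrow(runs),
    mode = "default", d = NA_integer_,
    counts = counts, C = ranks$C,
    thresholds = NULL, ptr_up = NULL, ptr_dn = NULL,
    records = NULL, includes_rc = NA
  ), class = "move_table")
}

#' @export
print.move_table <- function(x, ...) {
  cat(sprintf(
    "move_table: n = %d, r = %d run(s), %d row(s), mode = %s%s\n",
    x$n, x$r_original, x$nrows, x$mode,
    if (!is.na(x$d)) sprintf(" (d = %d)", x$d) else ""))
  cat(sprintf("  thresholds: %s; repositioning pointers: %s\n",
              if (is.null(x$thresholds)) "no" else "yes",
              if (is.null(x$ptr_up)) "no" else "yes"))
  invisible(x)
}

#' Locate the run containing a BWT offset
#'
#' Binary search over row start offsets; used only to initialise a cursor
#' (mid-query navigation never needs random entry).
#'
#' @param M A `move_table`.
#' @param j 0-based BWT offset.
#' @return A position: list with `run` (1-based row index) and `offset` (`j`).
#' @export
position_at <- function(M, j) {
  j <- as.integer(j)
  if (j < 0L || j >= M$n) stop("range error: offset out of range")
  list(run = findInterval(j, M$p), offset = j)
}

#' Fast-forward to the run containing a target offset
#'
#' Advances linearly through consecutive rows from `i` until reaching the
#' smallest row whose interval contains `j_target`, incrementing the
#' fast-forward counter by the number of rows advanced.
#'
#' @param M A `move_table`.
#' @param i 1-based starting row index with `M$p[i] <= j_target`.
#' @param j_target 0-based target offset.
#' @param counters Optional counters environment from [new_counters()].
#' @return 1-based row index containing `j_target`.
#' @export
fast_forward <- function(M, i, j_target, counters = NULL) {
  if (j_target >= M$n) stop("range error: target offset out of range")
  p <- M$p
  if (j_target < p[i]) stop("contract violation: target offset precedes row start")
  i2 <- i
  nr <- M$nrows
  while (i2 < nr && j_target >= p[i2 + 1L]) i2 <- i2 + 1L
  if (!is.null(counters)) {
    counters$fast_forwards <- counters$fast_forwards + (i2 - i)
  }
  i2
}

#' One LF-mapping step on the move table
#'
#' `j' = pi + (j - p)` for the current row, then a fast-forward from row `xi`
#' to the row containing `j'`. Agrees with [lf_oracle()] at every offset.
#'
#' @param M A `move_table`.
#' @param pos Position list (`run`, `offset`), e.g. from [position_at()].
#' @param counters Optional counters environment.
#' @return The new position.
#' @export
lf_move <- function(M, pos, counters = NULL) {
  i <- pos$run
  j <- pos$offset
  if (is.null(i) || i < 1L || i > M$nrows ||
      j < M$p[i] || j >= M$p[i] + M$l[i]) {
    stop("contract violation: invalid position")
  }
  j2 <- M$pi[i] + (j - M$p[i])
  i2 <- fast_forward(M, M$xi[i], j2, counters)
  if (!is.null(counters)) counters$lf_steps <- counters$lf_steps + 1L
  list(run = i2, offset = j2)
}
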