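# Run splitting (balancing) after Nishimoto & Tabei: subdivide BWT runs so
# that every LF-mapping needs fewer than 2d fast-forwards, adding at most
# ceil(r/(d-1)) rows. A row qualifies for splitting when its output interval
# (the pi-image [pi, pi+l)) strictly contains >= 2d input-interval (row) start
# points; it is then split at its d-th contained start. Splits are applied one
# at a time against the up-to-date start set until no row qualifies.

#' Split runs for a constant fast-forward bound
#'
#' Produces the "constant" mode table: LF results are unchanged at every
#' offset, row intervals still partition `[0, n)`, and after convergence the
#' maximum number of fast-forwards per LF step is `< 2d` while at most
#' `ceiling(r/(d-1))` rows have been added.
#'
#' @param M A `move_table` (thresholds/pointers, if any, are dropped and must
#'   be recomputed on the split table).
#' @param d Balancing parameter, integer `>= 2`. Default 4.
#' @param max_iterations Safety cap on the number of splits; exceeding it
#'   signals an implementation bug.
#' @return A `move_table` with `mode = "constant"` and `d` recorded;
#'   `r_original` is preserved from the input.
#' @export
split_runs <- function(M, d = 4L, max_iterations = NULL) {
  d <- as.integer(d)
  if (is.na(d) || d < 2L) stop("validation error: d must be an integer >= 2")
  if (is.null(max_iterations)) max_iterations <- 10L * M$nrows + 1000L

  code <- M$code
  l <- M$l
  p <- M$p
  pi <- M$pi
  iter <- 0L
  repeat {
    # starts strictly inside each output interval (pi, pi + l)
    lo <- findInterval(pi, p)
    cnt <- findInterval(pi + l - 1L, p) - lo
    i <- which(cnt >= 2L * d)
    if (length(i) == 0L) break
    i <- i[1L]
    s <- p[lo[i] + d]            # d-th row start inside (pi_i, pi_i + l_i)
    left <- s - pi[i]            # length of the left sub-run (>= 1)
    code <- append(code, code[i], after = i)
    l <- append(l, l[i] - left, after = i)
    l[i] <- left
    p <- append(p, p[i] + left, after = i)
    pi <- append(pi, s, after = i)
    iter <- iter + 1L
    if (iter > max_iterations) {
      stop("build error: run splitting failed to converge (implementation bug)")
    }
  }

  M$c <- MOVE_ALPHABET[code]
  M$code <- code
  M$l <- l
  M$p <- p
  M$pi <- pi
  M$xi <- findInterval(pi, p)
  M$nrows <- length(p)
  M$mode <- "constant"
  M$d <- d
  M$thresholds <- NULL
  M$ptr_up <- NULL
  M$ptr_dn <- NULL
  M
}

#' Verify the balancing bounds
#'
#' Sweeps every BWT offset, measuring the fast-forward count of the LF step
#' starting at that offset, and reports the maximum together with the number
#' of rows added by splitting.
#'
#' @param M A `move_table` (typically in constant mode).
#' @param d The balancing parameter the table was split with.
#' @return List with `max_ff`, `rows_added` and `bound_ok`
#'   (`max_ff < 2d && rows_added <= ceiling(r_original/(d-1))`).
#' @export
verify_balance <- function(M, d) {
  rowidx <- rep.int(seq_len(M$nrows), M$l)
  jp <- M$pi[rowidx] + (sequence(M$l) - 1L)
  dest <- findInterval(jp, M$p)
  ff <- dest - M$xi[rowidx]
  rows_added <- M$nrows - M$r_original
  list(max_ff = max(ff),
       rows_added = rows_added,
       bound_ok = max(ff) < 2L * d &&
         rows_added <= ceiling(M$r_original / (d - 1L)))
}
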