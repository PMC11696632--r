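# High-level index construction: text -> suffix array -> BWT -> move table
# (-> run splitting) -> thresholds (-> repositioning pointers).

#' Build a complete move-structure index
#'
#' Runs the whole build pipeline and returns a query-ready table. Thresholds
#' are always computed on the final (possibly split) table; constant mode
#' additionally stores repositioning pointers.
#'
#' @param x Input reference: a named character vector of DNA records, a path
#'   to a FASTA file, or an `index_text`.
#' @param mode `"default"` (no splitting) or `"constant"` (runs split with
#'   parameter `d`; bounded fast-forwards and pointer repositioning).
#' @param d Balancing parameter for constant mode (integer `>= 2`, default 4).
#' @param include_rc Index both strands (default `TRUE`); ignored when `x` is
#'   already an `index_text`.
#' @param alphabet_policy Passed to [build_text()].
#' @param keep_scaffold Attach the plain-BWT scaffold (suffix array, LCP,
#'   rank oracle) as `attr(, "scaffold")` for verification work.
#' @return A `move_table` with thresholds (and pointers in constant mode),
#'   plus the record table and strand flag of the indexed text.
#' @examples
#' idx <- build_index(c(x = "ACG"), include_rc = FALSE)
#' index_stats(idx)$r
#' @export
build_index <- function(x, mode = c("default", "constant"), d = 4L,
                        include_rc = TRUE,
                        alphabet_policy = c("strip", "reject"),
                        keep_scaffold = FALSE) {
  mode <- match.arg(mode)
  t <- if (inherits(x, "index_text")) {
    x
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             file.exists(x)) {
    build_text(read_fasta(x), include_rc = include_rc,
               alphabet_policy = alphabet_policy)
  } else {
    build_text(x, include_rc = include_rc, alphabet_policy = alphabet_policy)
  }
  scaf <- build_scaffold(t)
  runs <- run_length_encode(scaf$bwt)
  M <- build_move_table(runs, scaf$bwt, scaf$ranks)
  if (mode == "constant") M <- split_runs(M, d)
  M$thresholds <- compute_thresholds(M, scaf$bwt, scaf$lcp)
  if (mode == "constant") {
    ptrs <- build_reposition_pointers(M)
    M$ptr_up <- ptrs$up
    M$ptr_dn <- ptrs$dn
  }
  M$records <- t$record_boundaries
  M$includes_rc <- t$includes_rc
  if (keep_scaffold) attr(M, "scaffold") <- scaf
  M
}

#' Summary statistics of an index
#'
#' @param M A `move_table`.
#' @return List with `n`, `r` (runs before splitting), `rows` (table rows),
#'   `n_over_r`, `mode`, `d`, flags for thresholds/pointers, and the names of
#'   the per-query operation counters.
#' @export
index_stats <- function(M) {
  list(n = M$n, r = M$r_original, rows = M$nrows,
       n_over_r = M$n / M$r_original,
       mode = M$mode, d = M$d,
       has_thresholds = !is.null(M$thresholds),
       has_pointers = !is.null(M$ptr_up),
       includes_rc = M$includes_rc,
       counter_fields = c("lf_steps", "fast_forwards",
                          "reposition_scans", "case2_events"))
}
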