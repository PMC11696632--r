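# Query algorithms: pseudo-matching lengths (one right-to-left pass with a
# running match length that resets to 0 at every mismatch event), backward
# search for count queries (top/bottom pointer contraction), and the
# round-robin batched query loop.

# per-read PML state; one inner-loop step advances one query character
.pml_init <- function(M, read, name, start, use_pointers, counters) {
  qcodes <- .query_codes(read)
  list(name = name, qcodes = qcodes, i = length(qcodes),
       pos = start, ell = 0L, pml = integer(length(qcodes)),
       use_pointers = use_pointers, counters = counters,
       done = length(qcodes) == 0L)
}

.pml_step <- function(M, st) {
  i <- st$i
  k <- st$qcodes[i]
  if (is.na(k) || M$counts[k] == 0L) {
    # character outside the index alphabet / absent from the BWT:
    # record 0, reset the match length, hold the position
    st$ell <- 0L
  } else if (M$code[st$pos$run] == k) {
    # case 1: extend the match and take an LF step
    st$ell <- st$ell + 1L
    st$pml[i] <- st$ell
    st$pos <- lf_move(M, st$pos, st$counters)
  } else {
    # case 2: reposition to the nearest qualifying offset, reset, then LF
    if (!is.null(st$counters)) {
      st$counters$case2_events <- st$counters$case2_events + 1L
    }
    st$ell <- 0L
    pos2 <- if (st$use_pointers) {
      .reposition_pointer_code(M, st$pos, k,
                               list(up = M$ptr_up, dn = M$ptr_dn), st$counters)
    } else {
      .reposition_scan_code(M, st$pos, k, st$counters)
    }
    st$pos <- lf_move(M, pos2, st$counters)
  }
  st$i <- i - 1L
  st$done <- st$i < 1L
  st
}

.pml_result <- function(st) {
  structure(list(name = st$name, pmls = st$pml,
                 counters = if (is.null(st$counters)) NULL
                            else counters_snapshot(st$counters)),
            class = "query_result")
}

.as_start_position <- function(M, start) {
  if (is.null(start)) return(position_at(M, 0L))
  if (is.numeric(start)) return(position_at(M, start))
  start
}

#' Compute pseudo-matching lengths for one read
#'
#' Sweeps the read right-to-left with a running match length `ell` (initially
#' 0). If the BWT character at the cursor equals the query character (case 1),
#' `ell` is incremented, recorded, and an LF step taken; otherwise (case 2)
#' `ell` resets to 0, 0 is recorded, and the cursor repositions to the nearest
#' offset carrying the query character (direction chosen by the thresholds)
#' before the LF step. Characters outside `{A,C,G,T}` or absent from the BWT
#' record 0 and leave the cursor unchanged. PMLs are returned left-to-right in
#' read orientation.
#'
#' @param M A `move_table` with thresholds computed (see [build_index()]);
#'   constant-mode tables with stored pointers reposition via one dereference.
#' @param read Read sequence (character scalar).
#' @param name Read name carried into the result.
#' @param start Start position: `NULL` (offset 0), a 0-based BWT offset, or a
#'   position list. The start is arbitrary; a shared start makes runs
#'   comparable across modes.
#' @param use_pointers Use stored repositioning pointers (defaults to yes for
#'   constant-mode tables that carry them).
#' @param counters Counters environment; pass `NULL` to disable counting.
#' @return Object of class `query_result`: list with `name`, `pmls` (integer
#'   vector, read orientation) and a `counters` snapshot.
#' @examples
#' idx <- build_index(c(x = "ACG"), include_rc = FALSE)
#' compute_pmls(idx, "ACG")$pmls  # 3 2 1
#' @export
compute_pmls <- function(M, read, name = "read", start = NULL,
                         use_pointers = identical(M$mode, "constant") &&
                           !is.null(M$ptr_up),
                         counters = new_counters()) {
  if (is.null(M$thresholds)) {
    stop("configuration error: thresholds have not been computed")
  }
  if (use_pointers && is.null(M$ptr_up)) {
    stop("configuration error: repositioning pointers have not been built")
  }
  st <- .pml_init(M, read, name, .as_start_position(M, start),
                  use_pointers, counters)
  while (!st$done) st <- .pml_step(M, st)
  .pml_result(st)
}

#' Reference PML implementation on the plain BWT
#'
#' Runs the same right-to-left algorithm directly on the uncompressed BWT with
#' rank structures, choosing the repositioning side by explicit LCP comparison
#' ([reposition_oracle()]). Serves as the independent check that both move
#' table modes reproduce: the outputs must be identical.
#'
#' @param scaf A `bwt_scaffold` from [build_scaffold()].
#' @param read Read sequence.
#' @param start_offset 0-based starting BWT offset (default 0).
#' @return Integer PML vector, read orientation.
#' @export
pml_oracle <- function(scaf, read, start_offset = 0L) {
  qcodes <- .query_codes(read)
  m <- length(qcodes)
  pml <- integer(m)
  codes <- scaf$bwt$codes
  lf <- scaf$ranks$lf
  lcp <- scaf$lcp
  occ <- scaf$occ_by_code
  j <- as.integer(start_offset)
  ell <- 0L
  for (i in rev(seq_len(m))) {
    k <- qcodes[i]
    if (is.na(k) || length(occ[[k]]) == 0L) {
      ell <- 0L
      next
    }
    if (codes[j + 1L] == k) {
      ell <- ell + 1L
      pml[i] <- ell
      j <- lf[j + 1L]
    } else {
      ell <- 0L
      o <- occ[[k]]
      iu <- findInterval(j - 1L, o)
      id <- findInterval(j, o) + 1L
      jup <- if (iu >= 1L) o[iu] else NA_integer_
      jdn <- if (id <= length(o)) o[id] else NA_integer_
      jr <- if (is.na(jdn)) {
        jup
      } else if (is.na(jup)) {
        jdn
      } else if (.lcp_range_min(lcp, jup, j) >= .lcp_range_min(lcp, j, jdn)) {
        jup
      } else {
        jdn
      }
      j <- lf[jr + 1L]
    }
  }
  pml
}

#' Initial BWM range for a character
#'
#' The range of BWM rows prefixed by `c` is the F-column block
#' `[C[c], C[c] + count(c) - 1]` (inclusive).
#'
#' @param M A `move_table`.
#' @param c Character.
#' @return Object of class `bwm_range`: list with `top`, `bottom` positions
#'   and an `empty` flag.
#' @export
init_range <- function(M, c) {
  k <- .char_to_code(c)
  cnt <- unname(M$counts[k])
  if (cnt == 0L) {
    return(structure(list(top = NULL, bottom = NULL, empty = TRUE),
                     class = "bwm_range"))
  }
  top_off <- unname(M$C[k])
  structure(list(top = position_at(M, top_off),
                 bottom = position_at(M, top_off + cnt - 1L),
                 empty = FALSE),
            class = "bwm_range")
}

.empty_range <- function() {
  structure(list(top = NULL, bottom = NULL, empty = TRUE), class = "bwm_range")
}

#' One backward-search step
#'
#' Extends the matched suffix by `c` on the left. If the BWT character at the
#' top pointer differs from `c`, the top moves downward to the first offset
#' carrying `c` (the `jdn` direction); the bottom symmetrically moves upward
#' to the last such offset (`jup`). If the pointers cross or no qualifying
#' offset lies within the range, the result is empty; otherwise both pointers
#' advance by one LF step.
#'
#' @param M A `move_table`.
#' @param rng Non-empty `bwm_range`.
#' @param c Character to prepend.
#' @param counters Optional counters environment (scan rows are booked as
#'   repositioning scans).
#' @return Updated `bwm_range`.
#' @export
backward_extend <- function(M, rng, c, counters = NULL) {
  if (rng$empty) stop("contract violation: cannot extend an empty range")
  k <- .char_to_code(c)
  code <- M$code
  nr <- M$nrows

  top <- rng$top
  if (code[top$run] != k) {
    i2 <- top$run + 1L
    while (i2 <= nr && code[i2] != k) i2 <- i2 + 1L
    if (!is.null(counters)) {
      counters$reposition_scans <- counters$reposition_scans + (i2 - top$run)
    }
    if (i2 > nr) return(.empty_range())
    top <- list(run = i2, offset = M$p[i2])
  }
  bottom <- rng$bottom
  if (code[bottom$run] != k) {
    i2 <- bottom$run - 1L
    while (i2 >= 1L && code[i2] != k) i2 <- i2 - 1L
    if (!is.null(counters)) {
      counters$reposition_scans <- counters$reposition_scans + (bottom$run - i2)
    }
    if (i2 < 1L) return(.empty_range())
    bottom <- list(run = i2, offset = M$p[i2] + M$l[i2] - 1L)
  }
  if (top$offset > bottom$offset) return(.empty_range())

  structure(list(top = lf_move(M, top, counters),
                 bottom = lf_move(M, bottom, counters),
                 empty = FALSE),
            class = "bwm_range")
}

#' Count occurrences of a pattern (backward search)
#'
#' Initialises the range on the last pattern character, then applies
#' [backward_extend()] right-to-left. The final range width equals the number
#' of occurrences of the pattern in the indexed text (sentinel excluded).
#' Patterns containing characters outside `{A,C,G,T}` count 0.
#'
#' @param M A `move_table`.
#' @param pattern Pattern string.
#' @param counters Optional counters environment.
#' @return Integer occurrence count.
#' @examples
#' idx <- build_index(c(x = "AAAA"), include_rc = FALSE)
#' count_occurrences(idx, "AA")  # 3
#' @export
count_occurrences <- function(M, pattern, counters = NULL) {
  stopifnot(nchar(pattern) > 0L)
  qcodes <- .query_codes(pattern)
  if (anyNA(qcodes)) return(0L)
  m <- length(qcodes)
  rng <- init_range(M, substr(toupper(pattern), m, m))
  if (rng$empty) return(0L)
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  for (i in rev(seq_len(m - 1L))) {
    rng <- backward_extend(M, rng, chars[i], counters)
    if (rng$empty) return(0L)
  }
  rng$bottom$offset - rng$top$offset + 1L
}

#' Round-robin batched PML queries
#'
#' Processes up to `batch_size` reads concurrently in a single loop,
#' advancing each active read by one inner-loop step per turn and loading the
#' next read from the queue when one is exhausted. This mirrors the
#' latency-hiding scheduling structure (the batch size would steer hardware
#' prefetching; no prefetching is performed here). Results are identical to
#' sequential per-read processing, independent of `batch_size`, and emitted
#' in input order.
#'
#' @param M A `move_table` with thresholds (see [compute_pmls()]).
#' @param reads Named character vector of read sequences.
#' @param batch_size Number of concurrent reads, `>= 1` (default 16).
#' @param start Shared start position (as in [compute_pmls()]).
#' @param use_pointers As in [compute_pmls()].
#' @param with_counters Attach a per-read counters snapshot.
#' @return List of `query_result`, one per read, in input order.
#' @export
batch_query <- function(M, reads, batch_size = 16L, start = NULL,
                        use_pointers = identical(M$mode, "constant") &&
                          !is.null(M$ptr_up),
                        with_counters = TRUE) {
  stopifnot(batch_size >= 1L)
  if (is.null(M$thresholds)) {
    stop("configuration error: thresholds have not been computed")
  }
  nreads <- length(reads)
  nms <- names(reads)
  if (is.null(nms)) nms <- sprintf("read_%d", seq_len(nreads))
  start_pos <- .as_start_position(M, start)
  results <- vector("list", nreads)

  nslots <- min(batch_size, nreads)
  slots <- vector("list", nslots)
  slot_read <- integer(nslots)
  next_read <- 1L

  load_next <- function(s) {
    if (next_read > nreads) {
      slots[s] <<- list(NULL)  # mark slot idle (plain [[<- NULL would drop it)
      return(invisible())
    }
    cnt <- if (with_counters) new_counters() else NULL
    slots[[s]] <<- .pml_init(M, reads[[next_read]], nms[next_read],
                             start_pos, use_pointers, cnt)
    slot_read[s] <<- next_read
    next_read <<- next_read + 1L
  }
  for (s in seq_len(nslots)) load_next(s)

  repeat {
    active <- FALSE
    for (s in seq_len(nslots)) {
      st <- slots[[s]]
      if (is.null(st)) next
      active <- TRUE
      if (st$done) {
        results[[slot_read[s]]] <- .pml_result(st)
        load_next(s)
        next
      }
      st <- .pml_step(M, st)
      if (st$done) {
        results[[slot_read[s]]] <- .pml_result(st)
        load_next(s)
      } else {
        slots[[s]] <- st
      }
    }
    if (!active) break
  }
  results
}

#' Write PML results as plain text
#'
#' One record per read: a header line `>` + name, then one line of
#' space-separated integers in read orientation.
#'
#' @param results List of `query_result` (from [compute_pmls()] or
#'   [batch_query()]).
#' @param path Output file path.
#' @export
write_pml_output <- function(results, path) {
  lines <- unlist(lapply(results, function(r) {
    c(paste0(">", r$name), paste(r$pmls, collapse = " "))
  }))
  writeLines(lines, path)
}

#' Write count results as TSV
#'
#' @param names Pattern/read names.
#' @param counts Integer counts.
#' @param path Output file path.
#' @export
write_count_output <- function(names, counts, path) {
  utils::write.table(
    data.frame(read_name = names, count = counts, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}
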