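# Index serialization: a versioned, tab-separated text container. The format
# is documented here and in the README; round trips are field-exact, and a
# version/magic mismatch or truncation is detected on load.
#
#   #MOVEINDEX <TAB> 1              magic + format version
#   key <TAB> value                 header: n, r_original, nrows, mode, d,
#                                   includes_rc, has_thresholds, has_pointers,
#                                   alphabet
#   records <TAB> <k>               then k lines: name <TAB> start <TAB> end
#   rows <TAB> <nrows>              then nrows row lines:
#     c l p pi xi [thr$ thrA thrC thrG thrT]
#               [up$ upA upC upG upT dn$ dnA dnC dnG dnT]
#   #END                            trailer (truncation sentinel)
#
# Missing integers are encoded as ".".

.fmt_int <- function(x) ifelse(is.na(x), ".", as.character(x))
.parse_int <- function(x) {
  out <- suppressWarnings(as.integer(x))
  out[x == "."] <- NA_integer_
  out
}

#' Serialize an index to a file
#'
#' @param M A `move_table` (thresholds/pointers are written when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_index <- function(M, path) {
  has_thr <- !is.null(M$thresholds)
  has_ptr <- !is.null(M$ptr_up)
  header <- c(
    "#MOVEINDEX\t1",
    paste0("n\t", M$n),
    paste0("r_original\t", M$r_original),
    paste0("nrows\t", M$nrows),
    paste0("mode\t", M$mode),
    paste0("d\t", .fmt_int(M$d)),
    paste0("includes_rc\t",
           if (is.na(M$includes_rc)) "." else as.integer(M$includes_rc)),
    paste0("has_thresholds\t", as.integer(has_thr)),
    paste0("has_pointers\t", as.integer(has_ptr)),
    paste0("alphabet\t", paste(MOVE_ALPHABET, collapse = ""))
  )
  rec <- M$records
  if (is.null(rec)) {
    rec_lines <- "records\t0"
  } else {
    rec_lines <- c(paste0("records\t", nrow(rec)),
                   sprintf("%s\t%d\t%d", rec$name, rec$start, rec$end))
  }
  cols <- list(M$c, M$l, M$p, M$pi, M$xi)
  if (has_thr) cols <- c(cols, lapply(1:5, function(k) .fmt_int(M$thresholds[, k])))
  if (has_ptr) {
    cols <- c(cols,
              lapply(1:5, function(k) .fmt_int(M$ptr_up[, k])),
              lapply(1:5, function(k) .fmt_int(M$ptr_dn[, k])))
  }
  row_lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, rec_lines, paste0("rows\t", M$nrows), row_lines, "#END"),
             path)
  invisible(path)
}

#' Load an index from a file
#'
#' @param path Path to a file written by [serialize_index()].
#' @return The reconstructed `move_table`, field-exact.
#' @export
deserialize_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("load error: index file truncated or corrupt")
  magic <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(magic[1L], "#MOVEINDEX")) {
    stop("load error: not a move-structure index file (bad magic)")
  }
  if (!identical(magic[2L], "1")) {
    stop("load error: unsupported index format version '", magic[2L], "'")
  }
  if (!identical(lines[length(lines)], "#END")) {
    stop("load error: index file truncated or corrupt")
  }

  kv <- strsplit(lines[2:10], "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  need <- c("n", "r_original", "nrows", "mode", "d", "includes_rc",
            "has_thresholds", "has_pointers", "alphabet")
  if (!identical(keys, need)) stop("load error: malformed index header")
  h <- stats::setNames(as.list(vals), keys)
  n <- as.integer(h$n)
  nrows <- as.integer(h$nrows)
  has_thr <- h$has_thresholds == "1"
  has_ptr <- h$has_pointers == "1"

  pos <- 11L
  rec_head <- strsplit(lines[pos], "\t", fixed = TRUE)[[1L]]
  if (!identical(rec_head[1L], "records")) stop("load error: malformed record table")
  nrec <- as.integer(rec_head[2L])
  records <- NULL
  if (nrec > 0L) {
    rl <- strsplit(lines[pos + seq_len(nrec)], "\t", fixed = TRUE)
    records <- data.frame(name = vapply(rl, `[`, "", 1L),
                          start = as.integer(vapply(rl, `[`, "", 2L)),
                          end = as.integer(vapply(rl, `[`, "", 3L)),
                          stringsAsFactors = FALSE)
  }
  pos <- pos + nrec + 1L
  row_head <- strsplit(lines[pos], "\t", fixed = TRUE)[[1L]]
  if (!identical(row_head[1L], "rows") || as.integer(row_head[2L]) != nrows) {
    stop("load error: malformed row block")
  }
  if (length(lines) != pos + nrows + 1L) {
    stop("load error: index file truncated or corrupt")
  }
  rl <- strsplit(lines[pos + seq_len(nrows)], "\t", fixed = TRUE)
  ncol_expect <- 5L + (if (has_thr) 5L else 0L) + (if (has_ptr) 10L else 0L)
  if (any(lengths(rl) != ncol_expect)) {
    stop("load error: index file truncated or corrupt")
  }
  m <- matrix(unlist(rl), nrow = nrows, byrow = TRUE)

  cc <- m[, 1L]
  l <- as.integer(m[, 2L])
  p <- as.integer(m[, 3L])
  pi <- as.integer(m[, 4L])
  xi <- as.integer(m[, 5L])
  if (sum(l) != n) stop("load error: row lengths do not sum to n")
  code <- match(cc, MOVE_ALPHABET)
  counts <- integer(5L)
  agg <- rowsum(l, code)
  counts[as.integer(rownames(agg))] <- agg[, 1L]
  counts <- stats::setNames(counts, MOVE_ALPHABET)
  Cvec <- stats::setNames(c(0L, cumsum(counts)[-5L]), MOVE_ALPHABET)

  col <- 6L
  thresholds <- NULL
  if (has_thr) {
    thresholds <- matrix(.parse_int(m[, col:(col + 4L)]), nrow = nrows,
                         dimnames = list(NULL, MOVE_ALPHABET))
    class(thresholds) <- c("threshold_set", class(thresholds))
    col <- col + 5L
  }
  ptr_up <- ptr_dn <- NULL
  if (has_ptr) {
    ptr_up <- matrix(.parse_int(m[, col:(col + 4L)]), nrow = nrows,
                     dimnames = list(NULL, MOVE_ALPHABET))
    ptr_dn <- matrix(.parse_int(m[, (col + 5L):(col + 9L)]), nrow = nrows,
                     dimnames = list(NULL, MOVE_ALPHABET))
  }

  structure(list(
    c = cc, code = code, l = l, p = p, pi = pi, xi = xi,
    nrows = nrows, n = n, r_original = as.integer(h$r_original),
    mode = h$mode, d = .parse_int(h$d),
    counts = counts, C = Cvec,
    thresholds = thresholds, ptr_up = ptr_up, ptr_dn = ptr_dn,
    records = records,
    includes_rc = if (h$includes_rc == ".") NA else h$includes_rc == "1"
  ), class = "move_table")
}
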