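# Alphabet handling. Order is '$' < 'A' < 'C' < 'G' < 'T' (sentinel smallest),
# with internal integer codes 1..5. Query sequences are restricted to ACGT;
# anything else (N, lowercase after normalisation failures, '$') never matches.

#' Index alphabet
#'
#' The five-character alphabet of the indexed text, in sorting order:
#' the sentinel `$` (lexicographically smallest) followed by `A`, `C`,
#' `G`, `T`.
#'
#' @format Character vector of length 5.
#' @export
MOVE_ALPHABET <- c("$", "A", "C", "G", "T")

# byte -> code lookup (NA for anything outside the alphabet)
.code_map <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("$")] <- 1L
  m[utf8ToInt("A")] <- 2L
  m[utf8ToInt("C")] <- 3L
  m[utf8ToInt("G")] <- 4L
  m[utf8ToInt("T")] <- 5L
  m
})

.alphabet_ints <- utf8ToInt("$ACGT")

# encode a single string to integer codes (NA = outside alphabet)
.encode_chars <- function(x) .code_map[utf8ToInt(x)]

# decode integer codes back to a string
.decode_codes <- function(codes) intToUtf8(.alphabet_ints[codes])

# query-side codes: ACGT only, sentinel and everything else become NA
.query_codes <- function(x) {
  codes <- .code_map[utf8ToInt(toupper(x))]
  codes[!is.na(codes) & codes == 1L] <- NA_integer_
  codes
}

.char_to_code <- function(c) {
  k <- .code_map[utf8ToInt(c)[1L]]
  if (is.na(k)) stop("character '", c, "' is not in the index alphabet ($ACGT)")
  k
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
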