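#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide alphabet: base sets, complements, and match tables.
# All sequence routines in the package funnel through these tables so that
# degenerate codes behave identically everywhere (search, enzymes, patterns).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_SETS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# 4-bit encoding: A=1, C=2, G=4, T=8; a pattern letter matches a sequence
# letter when their bit sets intersect.
IUPAC_BITS <- vapply(IUPAC_SETS, function(s) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[s])
}, integer(1))

#' Check that a string is a valid IUPAC nucleotide sequence
#'
#' @param bases A single string.
#' @param what Label used in error messages.
#' @return Invisibly, `bases`. Errors (naming the first offending position)
#'   when a non-IUPAC character is present.
#' @export
check_iupac <- function(bases, what = "sequence") {
  stopifnot(is.character(bases), length(bases) == 1L)
  ch <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% IUPAC_CHARS))
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC character '%s' at position %d",
                 what, ch[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(bases)
}

# integer codes 1..15 indexing IUPAC_CHARS, preserving case separately
iupac_codes <- function(bases) {
  ch <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
  m <- match(ch, IUPAC_CHARS)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("non-IUPAC character '%s' at position %d", ch[bad], bad),
         call. = FALSE)
  }
  m
}

iupac_bits_vec <- function(bases) unname(IUPAC_BITS[iupac_codes(bases)])

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate codes map to their complements (R to Y, S to S, ...); character
#' case is preserved position-wise.
#'
#' @param bases A single IUPAC string.
#' @return The reverse complement string.
#' @examples
#' reverse_complement("GAATTC")
#' reverse_complement("ARn")
#' @export
reverse_complement <- function(bases) {
  check_iupac(bases)
  comp <- complement_bases(bases)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Base-wise complement (not reversed)
#' @inheritParams reverse_complement
#' @export
complement_bases <- function(bases) {
  check_iupac(bases)
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  up <- ch %in% names(IUPAC_COMPLEMENT)
  out <- ch
  out[up] <- IUPAC_COMPLEMENT[ch[up]]
  lo <- !up
  out[lo] <- tolower(IUPAC_COMPLEMENT[toupper(ch[lo])])
  paste(out, collapse = "")
}

# Does pattern letter p (IUPAC) admit sequence letter s (IUPAC)?  Pattern
# semantics: the concrete base must lie in the pattern set; for a degenerate
# sequence letter we require set intersection (used for site search on
# records that themselves contain ambiguity codes).
iupac_compatible <- function(p_bits, s_bits) bitwAnd(p_bits, s_bits) > 0L

# Sliding-window degenerate match of `pattern` against coded sequence bits.
# Returns 1-based start positions. Vectorised over the sequence; this is the
# workhorse behind the naive scan and candidate verification.
iupac_window_match <- function(seq_bits, pattern_bits) {
  n <- length(seq_bits); m <- length(pattern_bits)
  if (m == 0L || n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (i in seq_len(m)) {
    ok <- ok & (bitwAnd(seq_bits[i:(n - m + i)], pattern_bits[i]) > 0L)
  }
  which(ok)
}

is_palindrome_iupac <- function(pattern) {
  identical(toupper(pattern), toupper(reverse_complement(pattern)))
}
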