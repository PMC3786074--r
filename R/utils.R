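#' @importFrom stats setNames rgeom runif
#' @importFrom utils adist head tail write.table read.delim
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# Public file formats (GFF3, GenBank spans) are 1-based inclusive.

DOMAIN_LABELS <- c("ACC5", "DDOM", "ANTICODON", "TDOM", "ACC3")

#' Sanitize a DNA string to the ACGTN alphabet
#'
#' Uppercases and maps every non-ACGT IUPAC code (and anything else) to N.
#' N never matches any base, so ambiguity codes are treated as mismatches
#' throughout the package.
#'
#' @param x character scalar.
#' @return character scalar over ACGTN.
#' @keywords internal
sanitize_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Reverse complement of an ACGTN string
#' @param x character scalar.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split to a character vector of single bases.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Hamming mismatch counts of a pattern along a text
#'
#' Slides `pattern` (no indels) along `text` and returns, for every 0-based
#' start position, the number of mismatching positions. N mismatches
#' everything, including N.
#'
#' @param text,pattern character scalars (ACGTN).
#' @return integer vector of length `nchar(text) - nchar(pattern) + 1`
#'   (empty when the text is shorter than the pattern); element i is the
#'   mismatch count at 0-based start i - 1.
#' @keywords internal
hamming_scan <- function(text, pattern) {
  n <- nchar(text); m <- nchar(pattern)
  if (n < m) return(integer(0))
  tv <- chars(text); pv <- chars(pattern)
  mm <- integer(n - m + 1L)
  for (k in seq_len(m)) {
    seg <- tv[k:(n - m + k)]
    mm <- mm + as.integer(seg != pv[k] | seg == "N" | pv[k] == "N")
  }
  mm
}

# Random ACGT string with a given GC fraction (AT-rich plastid IGS default).
random_dna <- function(n, gc = 0.32) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substring by 0-based half-open interval
substr0 <- function(x, start0, end0) {
  if (end0 <= start0) return("")
  substr(x, start0 + 1L, end0)
}

# do two 0-based half-open intervals overlap?
overlaps0 <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

`%||%` <- function(a, b) if (is.null(a)) b else a
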