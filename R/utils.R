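# Internal helpers shared across modules.

MISSING_TOKEN <- "."

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' `N` is preserved.
#'
#' @param x Single nucleotide string (A/C/G/T/N).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 32-bit multiply modulo 2^32 in doubles (no precision loss: split operand).
mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

#' Deterministic 32-bit string hash (FNV-1a)
#'
#' Used for reproducible pattern identifiers and the surrogate binding
#' predictor. Pure R, platform independent.
#'
#' @param s Character scalar.
#' @return Double holding an integer in `[0, 2^32)`.
#' @export
fnv1a32 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b %% 256)
    h <- mul32(h, 16777619)
  }
  h
}

# XOR for doubles holding 32-bit values (bitwXor() only takes ints < 2^31).
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

# Length of common prefix / suffix of two character scalars (by residue).
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1L]][seq_len(n)]
  bv <- strsplit(b, "")[[1L]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b, max_len = NULL) {
  n <- min(nchar(a), nchar(b))
  if (!is.null(max_len)) n <- min(n, max_len)
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1L]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1L]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Is `needle` a substring of any string in `haystacks`?
is_substring_of_any <- function(needle, haystacks) {
  any(vapply(haystacks, function(h) grepl(needle, h, fixed = TRUE), logical(1L)))
}
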