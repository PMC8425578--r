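#' @importFrom stats dnorm rnorm runif setNames aggregate sd
#' @importFrom utils read.table write.table head tail
NULL

# Phred+33 bounds: scores 0..40 <-> ASCII 33..73
.Q_OFFSET <- 33L
.Q_MAX <- 40L

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of quality strings.
#' @param offset ASCII offset (default 33).
#' @return list of integer vectors, one per input string.
#' @export
qual_to_int <- function(qual, offset = 33L) {
  lapply(qual, function(s) utf8ToInt(s) - as.integer(offset))
}

#' Encode integer Phred scores as a quality string
#'
#' @param q integer vector of scores in [0, 40].
#' @param offset ASCII offset (default 33).
#' @return single quality string.
#' @export
int_to_qual <- function(q, offset = 33L) {
  if (length(q) == 0L) return("")
  intToUtf8(as.integer(q) + as.integer(offset))
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper over Biostrings for vectors of plain character sequences.
#'
#' @param x character vector over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse each string in a character vector (used for quality strings).
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Phred equivalent of an error probability
#'
#' Q = -10 * log10(p).  A probability of zero has no finite Phred value and is
#' returned as `Inf`.
#'
#' @param p numeric vector of probabilities in [0, 1].
#' @return numeric vector of Phred-scale values.
#' @export
phred_equivalent <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p == 0, Inf, -10 * log10(p))
}

# Hamming distance between one pattern and the same-length prefixes of many
# sequences.  Sequences shorter than the pattern get Inf.
prefix_hamming <- function(seqs, pattern) {
  L <- nchar(pattern)
  out <- rep(Inf, length(seqs))
  ok <- nchar(seqs) >= L
  if (any(ok)) {
    pref <- substr(seqs[ok], 1L, L)
    bytes <- matrix(charToRaw(paste(pref, collapse = "")), nrow = L)
    pb <- charToRaw(pattern)
    out[ok] <- colSums(bytes != pb)
  }
  out
}

# Minimum pairwise Levenshtein distance within a barcode set (base adist()).
min_pairwise_levenshtein <- function(x) {
  if (length(x) < 2L) return(Inf)
  d <- utils::adist(x)
  min(d[upper.tri(d)])
}

# Random DNA string helper used by simulator components.
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, "")
}
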