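#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm rbinom rpois runif optim fisher.test rnorm setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Extract a subsequence using 0-based half-open coordinates
#'
#' All genome coordinates inside this package are 0-based half-open
#' (BED-style); conversion to the 1-based inclusive conventions of
#' RepeatMasker `.out` and GFF3 happens only at format boundaries.
#'
#' @param seq a single DNA string.
#' @param start,end 0-based half-open interval, `0 <= start <= end <= nchar(seq)`.
#' @return the substring `[start, end)`.
#' @export
seq_slice <- function(seq, start, end) {
  stopifnot(start >= 0, end >= start, end <= nchar(seq))
  substr(seq, start + 1L, end)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T/N (case-insensitive).
#' @return reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Random DNA string
#'
#' Uniform i.i.d. bases; uses the current RNG stream so callers control
#' reproducibility with `set.seed()`.
#'
#' @param n length in bp.
#' @param gc GC content (probability of G or C at each site).
#' @return DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# split a DNA string into a character vector of single bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# TRUE at positions that are part of a CG dinucleotide (both the C and the G)
cpg_mask <- function(chars) {
  n <- length(chars)
  if (n < 2L) return(rep(FALSE, n))
  cg <- chars[-n] == "C" & chars[-1L] == "G"
  mask <- rep(FALSE, n)
  mask[which(cg)] <- TRUE
  mask[which(cg) + 1L] <- TRUE
  mask
}

# Hamming distance between two equal-length character vectors,
# optionally restricted to a column mask
hamming <- function(a, b, cols = NULL) {
  if (!is.null(cols)) {
    a <- a[cols]
    b <- b[cols]
  }
  sum(a != b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
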