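#' Derive a reproducible substream seed
#'
#' All stochastic stages draw their RNG state from a single global seed plus
#' a stream label, so that stages are reproducible independently of the
#' order in which they run.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the random stream (e.g. "alignments").
#' @return An integer seed, always in `[0, 2^31)`.
#' @examples
#' deriveSeed(1L, "genome")
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) %% 1000003L) * 7919 + h) %% 2147483629L
}

#' Signed fold-change convention
#'
#' A ratio r is reported as +r when r >= 1 and as -1/r when r < 1, so that
#' a halving and a doubling have the same magnitude with opposite signs.
#'
#' @param ratio Numeric vector of positive ratios.
#' @return Numeric vector of signed folds (|fold| >= 1), NA where the ratio
#'   is NA or non-finite.
#' @examples
#' signedFold(c(4, 1, 1/7))  # +4, +1, -7
#' @export
signedFold <- function(ratio) {
  out <- ifelse(ratio >= 1, ratio, -1 / ratio)
  out[!is.finite(ratio) | ratio < 0] <- NA_real_
  out
}

#' Convert a signed fold back to a ratio
#' @param fold Signed fold (|fold| >= 1).
#' @return Positive ratio.
#' @keywords internal
unsignFold <- function(fold) ifelse(fold >= 0, fold, -1 / fold)

# Standard stop codons (forward strand).
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Sample n codons uniformly from the 60 sense codons that are neither a
# stop nor ATG (avoids spurious nested starts where that matters).
randomCodons <- function(n, exclude_atg = FALSE) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  pool <- setdiff(all_codons, STOP_CODONS)
  if (exclude_atg) pool <- setdiff(pool, "ATG")
  sample(pool, n, replace = TRUE)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Overwrite genome[at..at+nchar(seq)-1] with seq (character genome).
spliceIn <- function(genome_chr, at, seq) {
  stopifnot(at >= 1, at + nchar(seq) - 1L <= nchar(genome_chr))
  paste0(
    substr(genome_chr, 1L, at - 1L),
    seq,
    substr(genome_chr, at + nchar(seq), nchar(genome_chr))
  )
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
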