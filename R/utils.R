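# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Vectorised over its input; `N` maps to `N`.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into a list of character vectors (one element per base).
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# PHRED quality <-> error probability
phred_to_error <- function(q) 10^(-q / 10)

error_to_phred <- function(e) -10 * log10(e)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Deterministic 32-bit sub-seed for a named pipeline stage, so stages can be
# re-run standalone yet reproduce the orchestrated run.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}
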