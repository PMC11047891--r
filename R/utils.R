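# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x character scalar over A, C, G, T, N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# smallest most-frequent value (deterministic mode)
mode_int <- function(x) {
  stopifnot(length(x) >= 1L, !anyNA(x))
  tb <- table(x)
  as.integer(min(as.integer(names(tb)[tb == max(tb)])))
}

# stop() with a consistent prefix for file-format problems
format_error <- function(...) {
  stop(..., call. = FALSE)
}
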