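# internal helpers

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate `n_sub` distinct positions of a sequence to a different base
mutate_positions <- function(seq, positions, alphabet = c("A", "C", "G", "T")) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
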