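#' Reverse-complement a DNA sequence
#'
#' Vectorised over its input. Sequences are plain uppercase DNA strings;
#' `N` is its own complement.
#'
#' @param x character vector of DNA sequences (alphabet A, C, G, T, N).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' revcomp(c("AAA", "GATTACA"))
#' @export
revcomp <- function(x) {
  normalize_dna(x) |>
    chartr(old = "ACGTN", new = "TGCAN") |>
    stringi_rev()
}

# base-R string reversal; avoids pulling in stringi directly
stringi_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Normalise a nucleotide string to uppercase DNA
#'
#' Uppercases and converts U to T so that reads, references and genome
#' compare directly in one alphabet.
#'
#' @param x character vector.
#' @return character vector over A, C, G, T, N.
#' @export
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", stringr::str_to_upper(x)))
}

# Random DNA with a given GC content; relies on the caller's RNG state.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Hamming distance between equal-length strings (no indels).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

assert_alphabet <- function(x, extra = "N", what = "sequence") {
  bad <- stringr::str_detect(x, paste0("[^ACGT", extra, "]"))
  if (any(bad)) {
    abort(sprintf("%s contains characters outside the DNA alphabet: %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}
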