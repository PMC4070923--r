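#' Reverse complement
#'
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of length n with a given A+T fraction (A/T and G/C equiprobable
# within their bins).
randomDNA <- function(n, at = 0.5) {
    p <- c(A = at / 2, T = at / 2, G = (1 - at) / 2, C = (1 - at) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
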