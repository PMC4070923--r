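#' Genetic codes and codon families
#'
#' Thin wrappers over the NCBI genetic-code tables shipped with Biostrings.
#' The package default is translation table 5 (invertebrate mitochondrial),
#' under which ATA encodes Met, TGA encodes Trp and AGA/AGG encode Ser, so
#' that AGN joins TCN in an eight-codon serine family.
#'
#' @param id NCBI translation table identifier as a string ("1" standard,
#'   "2" vertebrate mitochondrial, "5" invertebrate mitochondrial, ...).
#' @return `geneticCode()`: a named character vector mapping all 64 codons to
#'   one-letter amino acids, stops as `"*"`.
#' @examples
#' code <- geneticCode("5")
#' code[c("ATA", "TGA", "AGA")]
#' @export
geneticCode <- function(id = "5") {
    Biostrings::getGeneticCode(as.character(id))
}

#' @rdname geneticCode
#' @param code a genetic code as returned by [geneticCode()].
#' @return `stopCodons()`: character vector of stop codons under `code`.
#' @export
stopCodons <- function(code = geneticCode()) {
    names(code)[code == "*"]
}

#' @rdname geneticCode
#' @return `senseCodons()`: character vector of non-stop codons.
#' @export
senseCodons <- function(code = geneticCode()) {
    names(code)[code != "*"]
}

#' @rdname geneticCode
#' @return `codonFamilies()`: a named list, one character vector of synonymous
#'   codons per amino acid (stops under `"*"` included; drop that element for
#'   RSCU-style statistics).
#' @export
codonFamilies <- function(code = geneticCode()) {
    split(names(code), code)
}

# One-letter -> three-letter amino acid names, used when grouping codons by
# the amino acids the composition literature names (Pro, Ala, ...).
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Stop")

#' Translate a coding sequence
#'
#' Codon-by-codon translation of an in-frame CDS under an arbitrary NCBI
#' genetic code. Codons containing N translate to `X`.
#'
#' @param cds character(1) CDS, length a multiple of 3.
#' @param code genetic code from [geneticCode()].
#' @return character(1) amino-acid string (stops as `*`).
#' @export
translateCDS <- function(cds, code = geneticCode()) {
    stopifnot(nchar(cds) %% 3 == 0)
    if (nchar(cds) == 0L) return("")
    cod <- codonSplit(cds)
    aa <- unname(code[cod])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

# Split an in-frame CDS into its codons.
codonSplit <- function(cds) {
    n <- nchar(cds)
    if (n == 0L) return(character())
    substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Drop a trailing complete stop codon and/or an incomplete terminal codon
# (1-2 nt, polyadenylation-completed stops) from a CDS.
trimCDS <- function(cds, code = geneticCode(), dropStop = TRUE) {
    n <- nchar(cds)
    cds <- substr(cds, 1L, n - n %% 3L)
    if (dropStop && nchar(cds) >= 3L) {
        last <- substr(cds, nchar(cds) - 2L, nchar(cds))
        if (last %in% stopCodons(code))
            cds <- substr(cds, 1L, nchar(cds) - 3L)
    }
    cds
}
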