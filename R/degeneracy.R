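#' Degeneracy fold of a codon position
#'
#' A codon position is 4-fold degenerate when all four nucleotides at that
#' position preserve the encoded amino acid, 0-fold when only the observed
#' nucleotide does, and 2-fold otherwise (3-fold positions, which occur under
#' the standard code, are binned with 2-fold: the three-way scheme used for
#' mitochondrial site classes has no 3-fold bin).
#'
#' @param codon character(1) trinucleotide over A/C/G/T; not a stop codon.
#' @param position 1, 2 or 3.
#' @param code genetic code from [geneticCode()].
#' @return character(1): "0", "2" or "4".
#' @examples
#' siteFold("GGA", 3)  # "4": GGN all Gly
#' siteFold("ATT", 3)  # "2": ATT/ATC Ile, ATA/ATG Met (table 5)
#' siteFold("AGA", 3)  # "4" under table 5: AGN and UCN are all Ser
#' @export
siteFold <- function(codon, position, code = geneticCode()) {
    codon <- toupper(codon)
    if (!position %in% 1:3) stop("position must be 1, 2 or 3")
    if (grepl("[^ACGT]", codon) || nchar(codon) != 3L)
        stop("codon must be a trinucleotide over A/C/G/T, got '", codon, "'")
    if (code[[codon]] == "*") stop("'", codon, "' is a stop codon")
    unname(foldTable(code)[codon, position])
}

# Fold-class lookup: 64 x 3 character matrix ("0"/"2"/"4", NA rows for
# stops), built once per code and cached.
foldTable <- local({
    cache <- list()
    function(code = geneticCode()) {
        key <- paste(code, collapse = "")
        if (!is.null(cache[[key]])) return(cache[[key]])
        nts <- c("A", "C", "G", "T")
        ft <- matrix(NA_character_, 64, 3,
                     dimnames = list(names(code), NULL))
        for (cod in names(code)) {
            aa <- code[[cod]]
            if (aa == "*") next
            for (p in 1:3) {
                alt <- vapply(nts, function(n) {
                    x <- cod
                    substr(x, p, p) <- n
                    code[[x]]
                }, character(1))
                n <- sum(alt == aa)
                ft[cod, p] <- if (n == 4L) "4" else if (n == 1L) "0" else "2"
            }
        }
        cache[[key]] <<- ft
        ft
    }
})

#' Classify every codon site of a gene
#'
#' Applies [siteFold()] to each position of each codon of an in-frame CDS.
#' The terminal stop (complete, or a 1-2 nt incomplete remainder) is removed
#' first. Codons containing N are skipped with a message; an internal stop
#' codon is an error naming the codon index.
#'
#' @param cds character(1) CDS.
#' @param code genetic code from [geneticCode()].
#' @return data.frame with columns \code{codon_index}, \code{position}
#'   (1..3), \code{site} (position in the trimmed CDS), \code{codon} and
#'   \code{fold} ("0"/"2"/"4").
#' @export
classifyGene <- function(cds, code = geneticCode()) {
    cds <- trimCDS(toupper(cds), code)
    if (!nzchar(cds))
        return(data.frame(codon_index = integer(), position = integer(),
                          site = integer(), codon = character(),
                          fold = character()))
    cod <- codonSplit(cds)
    hasN <- grepl("N", cod, fixed = TRUE)
    if (any(hasN))
        message(sum(hasN), " codon(s) containing N skipped")
    isStop <- !hasN & code[cod] == "*"
    if (any(isStop))
        stop("internal stop codon at codon index ", which(isStop)[1])
    ft <- foldTable(code)
    keep <- which(!hasN)
    data.frame(
        codon_index = rep(keep, each = 3L),
        position = rep(1:3, length(keep)),
        site = as.integer(t(outer((keep - 1L) * 3L, 1:3, "+"))),
        codon = rep(cod[keep], each = 3L),
        fold = as.character(t(ft[cod[keep], , drop = FALSE])))
}

#' Per-site class assignment across a codon-aligned ortholog set
#'
#' Assigns each alignment column a degeneracy class. Under the default
#' \code{"concordant"} rule a site keeps a class only if every species whose
#' codon is unambiguous agrees on the fold at that position; discordant sites
#' get \code{NA} and are excluded from class statistics. The
#' \code{"reference"} rule instead takes the class from one reference
#' species, for sensitivity analysis.
#'
#' @param orthologSet named character vector of codon-aligned CDS strings
#'   (equal lengths, multiple of 3; terminal stops should already be absent).
#'   Gap characters `-` and N yield NA classes for that species.
#' @param code genetic code from [geneticCode()].
#' @param rule "concordant" (default) or "reference".
#' @param reference species name or index used by the "reference" rule.
#' @return character vector, one of "0"/"2"/"4" or NA per alignment position.
#' @export
assignSiteClasses <- function(orthologSet, code = geneticCode(),
                              rule = c("concordant", "reference"),
                              reference = 1L) {
    rule <- match.arg(rule)
    orthologSet <- unlist(as.list(orthologSet))
    if (length(orthologSet) < 1L) stop("empty ortholog set")
    L <- unique(nchar(orthologSet))
    if (length(L) != 1L)
        stop("sequences are not aligned (unequal lengths)")
    if (L %% 3L != 0L) stop("alignment length is not a multiple of 3")
    ft <- foldTable(code)
    perSpecies <- vapply(orthologSet, function(s) {
        cod <- codonSplit(toupper(s))
        ok <- !grepl("[^ACGT]", cod)
        stopHit <- ok & code[cod] == "*"
        if (any(stopHit))
            stop("stop codon in alignment at codon index ",
                 which(stopHit)[1])
        cls <- matrix(NA_character_, 3L, length(cod))
        cls[, ok] <- t(ft[cod[ok], , drop = FALSE])
        as.vector(cls)
    }, character(L))
    if (rule == "reference") {
        perSpecies[, reference]
    } else {
        # concordant: all species unambiguous and agreeing on the fold
        agree <- rowSums(perSpecies == perSpecies[, 1L]) ==
                 ncol(perSpecies)
        out <- perSpecies[, 1L]
        out[is.na(agree) | !agree] <- NA_character_
        out
    }
}

#' Class-conditional A+T content across species
#'
#' For each degeneracy class, computes each species' A+T fraction over the
#' alignment sites assigned to that class (sites where the species itself has
#' a gap or N are excluded for that species), then the mean and sample
#' standard deviation (n-1) across species — the form in which class-wise
#' A+T is tabulated across taxa.
#'
#' @inheritParams assignSiteClasses
#' @param classes optional precomputed output of [assignSiteClasses()].
#' @return data.frame with columns \code{fold}, \code{n_sites},
#'   \code{at_mean} and \code{at_sd} (percentages; NA when a class has no
#'   sites), plus an attribute \code{"perSpecies"}: the species x class
#'   matrix of A+T percentages.
#' @export
classComposition <- function(orthologSet, code = geneticCode(),
                             rule = c("concordant", "reference"),
                             reference = 1L, classes = NULL) {
    orthologSet <- unlist(as.list(orthologSet))
    if (is.null(classes))
        classes <- assignSiteClasses(orthologSet, code, rule, reference)
    mat <- do.call(rbind, strsplit(toupper(orthologSet), ""))
    per <- matrix(NA_real_, nrow(mat), 3L,
                  dimnames = list(names(orthologSet), c("0", "2", "4")))
    nSites <- integer(3L)
    for (k in 1:3) {
        cl <- c("0", "2", "4")[k]
        idx <- which(!is.na(classes) & classes == cl)
        nSites[k] <- length(idx)
        if (!length(idx)) next
        for (i in seq_len(nrow(mat))) {
            b <- mat[i, idx]
            b <- b[b %in% c("A", "C", "G", "T")]
            per[i, k] <- if (length(b)) 100 * mean(b %in% c("A", "T"))
                         else NA_real_
        }
    }
    out <- data.frame(
        fold = c("0", "2", "4"), n_sites = nSites,
        at_mean = apply(per, 2L, function(x) mean(x, na.rm = TRUE)),
        at_sd = apply(per, 2L, function(x) stats::sd(x[!is.na(x)])))
    out$at_mean[out$n_sites == 0L] <- NA_real_
    out$at_sd[out$n_sites == 0L] <- NA_real_
    rownames(out) <- NULL
    attr(out, "perSpecies") <- per
    out
}
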