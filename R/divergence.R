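#' Proportion of differing sites within a site class
#'
#' p-distance between two codon-aligned sequences restricted to a set of
#' alignment positions (typically the sites of one degeneracy class). Sites
#' where either sequence has a gap or ambiguity code are excluded pairwise.
#'
#' @param a,b equal-length aligned sequences.
#' @param sites integer vector of 1-based alignment positions; non-empty.
#' @return list with \code{p} (proportion differing), \code{diff} (raw count
#'   of differing sites) and \code{n} (sites compared after pairwise
#'   deletion).
#' @export
pairwiseClassPDistance <- function(a, b, sites) {
    if (length(sites) == 0L) stop("empty site set")
    if (nchar(a) != nchar(b)) stop("sequences must be aligned")
    ca <- chars(toupper(a))[sites]
    cb <- chars(toupper(b))[sites]
    ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
    n <- sum(ok)
    if (n == 0L)
        return(list(p = NA_real_, diff = 0L, n = 0L))
    d <- sum(ca[ok] != cb[ok])
    list(p = d / n, diff = d, n = n)
}

#' Jukes-Cantor distance
#'
#' \code{d = -(3/4) log(1 - 4p/3)}, the one-parameter multiple-hit
#' correction of a nucleotide p-distance. Undefined (saturated) at
#' \code{p >= 0.75}.
#'
#' @param p proportion of differing sites.
#' @return corrected distance (NaN/Inf for saturated input).
#' @export
jcDistance <- function(p) {
    -0.75 * log(1 - 4 * p / 3)
}

#' Class-conditional nucleotide substitution frequency
#'
#' Mean pairwise distance over all unordered species pairs, restricted to the
#' alignment sites of one degeneracy class. With \code{correction = "JC"}
#' (default) each pairwise p-distance is Jukes-Cantor corrected; published
#' class-wise frequencies exceeding 1 per site require a multiple-hit
#' correction, and JC is the minimal one. Pairs at or beyond the JC
#' saturation point (p >= 0.75) are excluded with a warning; it is an error
#' when every pair is saturated.
#'
#' @param orthologSet named character vector of codon-aligned CDS strings.
#' @param fold "0", "2" or "4".
#' @param code genetic code from [geneticCode()].
#' @param correction "JC" or "none".
#' @param classes optional precomputed [assignSiteClasses()] output.
#' @inheritParams assignSiteClasses
#' @return list with \code{fold}, \code{frequency} (mean pairwise distance;
#'   NA when the class has no sites), \code{n_sites}, \code{raw_total}
#'   (summed raw substitution counts over all pairs, saturated ones
#'   included) and \code{pairs} (per-pair data.frame: species1, species2,
#'   n, diff, p, d, saturated).
#' @examples
#' o <- c(a = "GGAGGAGGA", b = "GGAGGAGGA")
#' classSubstitutionFrequency(o, "4")$frequency  # identical -> 0
#' @export
classSubstitutionFrequency <- function(orthologSet, fold,
                                       code = geneticCode(),
                                       correction = c("JC", "none"),
                                       classes = NULL,
                                       rule = c("concordant", "reference"),
                                       reference = 1L) {
    correction <- match.arg(correction)
    fold <- match.arg(as.character(fold), c("0", "2", "4"))
    orthologSet <- unlist(as.list(orthologSet))
    if (length(orthologSet) < 2L) stop("need at least 2 species")
    if (is.null(classes))
        classes <- assignSiteClasses(orthologSet, code, rule, reference)
    sites <- which(!is.na(classes) & classes == fold)
    sp <- names(orthologSet)
    if (is.null(sp)) sp <- paste0("sp", seq_along(orthologSet))
    pairsIdx <- utils::combn(length(orthologSet), 2L)
    if (length(sites) == 0L) {
        return(list(fold = fold, frequency = NA_real_, n_sites = 0L,
                    raw_total = 0L, pairs = NULL))
    }
    rows <- lapply(seq_len(ncol(pairsIdx)), function(k) {
        i <- pairsIdx[1, k]; j <- pairsIdx[2, k]
        pd <- pairwiseClassPDistance(orthologSet[[i]], orthologSet[[j]],
                                     sites)
        sat <- !is.na(pd$p) && correction == "JC" && pd$p >= 0.75
        d <- if (is.na(pd$p) || sat) NA_real_
             else if (correction == "JC") jcDistance(pd$p) else pd$p
        data.frame(species1 = sp[i], species2 = sp[j], n = pd$n,
                   diff = pd$diff, p = pd$p, d = d, saturated = sat)
    })
    pairs <- do.call(rbind, rows)
    usable <- !pairs$saturated & !is.na(pairs$p)
    if (any(pairs$saturated))
        warning(sum(pairs$saturated), " saturated pair(s) (p >= 0.75) ",
                "excluded from the ", fold, "-fold frequency")
    if (!any(usable))
        stop("all species pairs are saturated at ", fold, "-fold sites")
    list(fold = fold,
         frequency = mean(pairs$d[usable]),
         n_sites = length(sites),
         raw_total = sum(pairs$diff),
         pairs = pairs)
}

#' Substitution-count ratios between degeneracy classes
#'
#' R_class = (summed raw pairwise substitution count at the class's sites) /
#' (summed count over all three classes). Raw counts, not corrected
#' distances, keep the ratios well-defined near saturation; the three ratios
#' sum to 1 by construction.
#'
#' @inheritParams classSubstitutionFrequency
#' @return named numeric vector \code{c("0" = , "2" = , "4" = )}.
#' @export
classRatios <- function(orthologSet, code = geneticCode(), classes = NULL,
                        rule = c("concordant", "reference"),
                        reference = 1L) {
    orthologSet <- unlist(as.list(orthologSet))
    if (is.null(classes))
        classes <- assignSiteClasses(orthologSet, code, rule, reference)
    counts <- vapply(c("0", "2", "4"), function(f) {
        sites <- which(!is.na(classes) & classes == f)
        if (!length(sites)) return(0L)
        pairsIdx <- utils::combn(length(orthologSet), 2L)
        sum(vapply(seq_len(ncol(pairsIdx)), function(k)
            pairwiseClassPDistance(orthologSet[[pairsIdx[1, k]]],
                                   orthologSet[[pairsIdx[2, k]]],
                                   sites)$diff, integer(1)))
    }, integer(1))
    tot <- sum(counts)
    if (tot == 0L) stop("zero substitutions in every class")
    counts / tot
}

#' Poisson-corrected amino-acid distance
#'
#' \code{d = -log(1 - p)} where p is the proportion of differing residues of
#' two aligned protein sequences; gap/X positions are excluded pairwise.
#' Saturation (p = 1) is an error (infinite distance).
#'
#' @param a,b equal-length aligned amino-acid strings.
#' @return numeric(1) distance.
#' @examples
#' poissonAADistance("MKLV", "MKLV")  # 0
#' @export
poissonAADistance <- function(a, b) {
    if (nchar(a) != nchar(b)) stop("proteins must be aligned")
    ca <- chars(toupper(a))
    cb <- chars(toupper(b))
    ok <- !(ca %in% c("-", "X", "*")) & !(cb %in% c("-", "X", "*"))
    if (!any(ok)) stop("no comparable residues")
    p <- mean(ca[ok] != cb[ok])
    if (p >= 1) stop("saturated protein pair (p = 1): infinite distance")
    -log(1 - p)
}

#' Overall average amino-acid distance (ASD)
#'
#' Pairwise Poisson-corrected distances among aligned ortholog proteins and
#' their overall mean (the mean of the upper triangle), the single-number
#' summary of how diverged one protein is across a set of taxa.
#'
#' @param proteins named character vector of aligned amino-acid strings
#'   (>= 2 species).
#' @return list with \code{matrix} (symmetric, zero diagonal) and \code{asd}.
#' @export
overallASD <- function(proteins) {
    proteins <- unlist(as.list(proteins))
    n <- length(proteins)
    if (n < 2L) stop("need at least 2 species")
    sp <- names(proteins)
    if (is.null(sp)) sp <- paste0("sp", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(sp, sp))
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            m[i, j] <- m[j, i] <- poissonAADistance(proteins[[i]],
                                                    proteins[[j]])
    list(matrix = m, asd = mean(m[upper.tri(m)]))
}
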