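#' Base composition of a sequence or region
#'
#' Exact A/C/G/T counts and percentages. N characters are counted but
#' excluded from the percentage denominator. Percentages in downstream
#' reports are rounded to 1 decimal place, half-up; the values returned here
#' are unrounded.
#'
#' @param seq character(1) DNA string (A/C/G/T/N).
#' @param region optional label carried into the result.
#' @return one-row data.frame with counts \code{A,C,G,T,N}, \code{length}
#'   (excluding N), percentages \code{pctA..pctT} and \code{pctAT}.
#' @examples
#' baseComposition("AATT")$pctAT   # 100
#' @export
baseComposition <- function(seq, region = NA_character_) {
    if (!nzchar(seq)) stop("empty sequence")
    f <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
    cnt <- f[c("A", "C", "G", "T")]
    nN <- unname(f["N"])
    denom <- sum(cnt)
    if (denom == 0L) stop("sequence contains no unambiguous bases")
    pct <- 100 * cnt / denom
    data.frame(region = region, length = denom, N = nN,
               A = unname(cnt["A"]), C = unname(cnt["C"]),
               G = unname(cnt["G"]), T = unname(cnt["T"]),
               pctA = unname(pct["A"]), pctC = unname(pct["C"]),
               pctG = unname(pct["G"]), pctT = unname(pct["T"]),
               pctAT = unname(pct["A"] + pct["T"]))
}

#' Composition by codon position
#'
#' Pools the bases at codon positions 1, 2 and 3 (on the coding strand)
#' across a set of coding sequences and returns one composition profile per
#' position. Each CDS is trimmed to a multiple of 3 (an incomplete terminal
#' codon is dropped).
#'
#' @param cdsSet character vector of CDS strings, each at least 3 nt.
#' @return data.frame of three [baseComposition()] rows, regions
#'   \code{pos1..pos3}.
#' @export
compositionByCodonPosition <- function(cdsSet) {
    cdsSet <- unlist(as.list(cdsSet))
    if (any(nchar(cdsSet) < 3L)) stop("every CDS must be at least 3 nt")
    per <- lapply(1:3, function(p) {
        pooled <- paste(vapply(cdsSet, function(s) {
            s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
            paste(chars(s)[seq(p, nchar(s), by = 3L)], collapse = "")
        }, character(1)), collapse = "")
        baseComposition(pooled, region = paste0("pos", p))
    })
    do.call(rbind, per)
}

#' Region-wise composition table for an annotated genome
#'
#' Convenience wrapper producing one composition row for the whole genome and
#' one per feature kind (PCGs, tRNAs, rRNAs, CR), computed on the coding
#' strand of each feature.
#'
#' @param genome a [MitoGenome-class].
#' @param gt a [GeneTable-class].
#' @return data.frame of [baseComposition()] rows.
#' @export
regionComposition <- function(genome, gt) {
    seqs <- featureSequences(genome, gt)
    kinds <- features(gt)$kind
    rows <- list(baseComposition(as.character(genomeSeq(genome)), "whole"))
    for (k in c("PCG", "tRNA", "rRNA", "CR")) {
        if (!any(kinds == k)) next
        rows[[length(rows) + 1L]] <-
            baseComposition(paste(seqs[kinds == k], collapse = ""), k)
    }
    do.call(rbind, rows)
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if all
#' codons of its synonymous family were used equally:
#' \code{RSCU(c) = count(c) * family_size / family_total}. Families are
#' defined by the genetic code. Codons of a family with zero observations get
#' \code{NA} (undefined), not 0.
#'
#' Stop codons are excluded by default (the codon-usage convention); set
#' \code{includeStops = TRUE} to score UAA/UAG-style rows as their own family,
#' as some published codon-usage tables do. Each CDS is trimmed to a multiple
#' of 3 and, unless \code{includeStops}, its terminal complete stop codon is
#' dropped before counting.
#'
#' @param cdsSet character vector of CDS strings.
#' @param code genetic code from [geneticCode()].
#' @param strands optional character vector (J/N, parallel to `cdsSet`) used
#'   with `strandSubset`.
#' @param strandSubset "all" (default), "J" or "N": restrict counting to the
#'   coding sequences on one strand.
#' @param includeStops logical(1), see above.
#' @return data.frame with columns \code{aa} (one-letter), \code{codon},
#'   \code{count}, \code{rscu}, ordered by amino acid.
#' @examples
#' # family {TTT, TTC} observed {3, 1} -> RSCU {1.5, 0.5}
#' t <- rscu(c("TTTTTTTTTTTC"))
#' t[t$aa == "F", ]
#' @export
rscu <- function(cdsSet, code = geneticCode(), strands = NULL,
                 strandSubset = c("all", "J", "N"), includeStops = FALSE) {
    strandSubset <- match.arg(strandSubset)
    cdsSet <- unlist(as.list(cdsSet))
    if (strandSubset != "all") {
        if (is.null(strands) || length(strands) != length(cdsSet))
            stop("strandSubset needs a 'strands' vector parallel to cdsSet")
        cdsSet <- cdsSet[strands == strandSubset]
    }
    counts <- countCodons(cdsSet, code,
                          dropTerminalStop = !includeStops)
    keep <- if (includeStops) names(code) else senseCodons(code)
    counts <- counts[keep]
    fam <- split(keep, code[keep])
    rows <- lapply(names(fam), function(a) {
        cods <- fam[[a]]
        tot <- sum(counts[cods])
        rs <- if (tot == 0) rep(NA_real_, length(cods))
              else counts[cods] * length(cods) / tot
        data.frame(aa = a, codon = cods, count = unname(counts[cods]),
                   rscu = unname(rs))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Codon counts over a CDS set; codons containing N or other ambiguity codes
# are skipped. Unknown (non-IUPAC) characters are an error.
countCodons <- function(cdsSet, code = geneticCode(),
                        dropTerminalStop = TRUE) {
    counts <- stats::setNames(integer(64), names(code))
    for (s in cdsSet) {
        bad <- setdiff(unique(chars(toupper(s))),
                       c("A", "C", "G", "T", "N"))
        if (length(bad))
            stop("unknown characters in CDS: ", paste(bad, collapse = ", "))
        s <- trimCDS(toupper(s), code, dropStop = dropTerminalStop)
        if (!nzchar(s)) next
        cod <- codonSplit(s)
        cod <- cod[!grepl("N", cod, fixed = TRUE)]
        t <- table(cod)
        counts[names(t)] <- counts[names(t)] + as.integer(t)
    }
    counts
}

# Amino acids the composition literature calls G+C-rich / A+T-rich, keyed by
# whether their codons are dominated by G/C or A/T at the first two positions.
GC_RICH_AA <- c("P", "A", "R", "G")   # Pro, Ala, Arg, Gly
AT_RICH_AA <- c("F", "I", "M", "Y", "N", "K")  # Phe Ile Met Tyr Asn Lys

#' Ratio of G+C-rich to A+T-rich codons
#'
#' Total codon count for the G+C-rich amino acids (Pro, Ala, Arg, Gly)
#' divided by the total for the A+T-rich amino acids (Phe, Ile, Met, Tyr,
#' Asn, Lys). Membership is by amino-acid family, not by codon base content.
#'
#' @param usage a codon-usage table from [rscu()].
#' @return numeric(1) ratio.
#' @examples
#' gcAtRichCodonRatio(rscu(c("GGAGGATTTTTTTTTTTT")))  # 2 Gly / 4 Phe = 0.5
#' @export
gcAtRichCodonRatio <- function(usage) {
    stopifnot(all(c("aa", "count") %in% colnames(usage)))
    num <- sum(usage$count[usage$aa %in% GC_RICH_AA])
    den <- sum(usage$count[usage$aa %in% AT_RICH_AA])
    if (den == 0) stop("no codons for the A+T-rich amino acids")
    num / den
}

#' Half-up rounding
#'
#' Rounds at \code{digits} decimals with ties away from zero, the convention
#' used when printing percentage tables (base \code{round()} is half-even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}
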