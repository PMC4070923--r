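#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

#' MitoGenome: a circular mitochondrial genome sequence
#'
#' Container for one mitogenome: an accession-like identifier, the J-strand
#' (majority-strand) sequence as a \link[Biostrings]{DNAString}, and a
#' circularity flag. All coordinates used elsewhere in the package are 1-based
#' inclusive positions on this sequence.
#'
#' @slot id character(1), accession-like identifier.
#' @slot seq \link[Biostrings]{DNAString}, alphabet restricted to A, C, G, T, N.
#' @slot circular logical(1); insect mitogenomes are closed circles, so this
#'   defaults to \code{TRUE}.
#'
#' @seealso [MitoGenome()] for the constructor, [GeneTable-class] for the
#'   annotation, [extractFeatureSequence()].
#' @exportClass MitoGenome
setClass("MitoGenome",
    representation(id = "character", seq = "ANY", circular = "logical"))

setValidity("MitoGenome", function(object) {
    msg <- character()
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (!is(object@seq, "DNAString"))
        msg <- c(msg, "'seq' must be a DNAString")
    else if (length(object@seq) == 0L)
        msg <- c(msg, "genome sequence must be non-empty")
    else {
        bad <- setdiff(names(which(
            Biostrings::alphabetFrequency(object@seq) > 0)),
            c("A", "C", "G", "T", "N"))
        if (length(bad))
            msg <- c(msg, paste0("sequence contains letters outside ",
                "{A,C,G,T,N}: ", paste(bad, collapse = ", ")))
    }
    if (length(object@circular) != 1L || is.na(object@circular))
        msg <- c(msg, "'circular' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' GeneTable: ordered annotation of a circular mitogenome
#'
#' One row per annotated feature (protein-coding gene, tRNA, rRNA or the
#' control region), with 1-based inclusive coordinates on the J strand and a
#' strand code: \code{J} for the majority strand, \code{N} for the minority
#' strand. A feature whose \code{end} is smaller than its \code{start} wraps
#' the origin of the circle; its length is \code{end + L - start + 1}.
#'
#' @slot features a \link[S4Vectors]{DataFrame} with columns \code{gene},
#'   \code{strand} (J/N), \code{start}, \code{end}, \code{kind}
#'   (PCG/tRNA/rRNA/CR) and \code{anticodon} (NA for non-tRNAs), sorted by
#'   \code{start}.
#' @slot genomeLength integer(1), length of the circle in bp.
#'
#' @seealso [readGeneTable()], [computeBoundaries()], [featureLengths()].
#' @exportClass GeneTable
setClass("GeneTable",
    representation(features = "DataFrame", genomeLength = "integer"))

setValidity("GeneTable", function(object) {
    msg <- character()
    need <- c("gene", "strand", "start", "end", "kind", "anticodon")
    df <- object@features
    if (!all(need %in% colnames(df)))
        return(paste("features must have columns",
                     paste(need, collapse = ", ")))
    L <- object@genomeLength
    if (length(L) != 1L || is.na(L) || L <= 0L)
        msg <- c(msg, "'genomeLength' must be a positive integer")
    if (nrow(df)) {
        if (!all(df$strand %in% c("J", "N")))
            msg <- c(msg, "strand must be 'J' or 'N'")
        if (!all(df$kind %in% c("PCG", "tRNA", "rRNA", "CR")))
            msg <- c(msg, "kind must be one of PCG, tRNA, rRNA, CR")
        if (anyNA(df$start) || anyNA(df$end) ||
            any(df$start < 1L) || any(df$end < 1L) ||
            (!anyNA(L) && length(L) == 1L &&
             (any(df$start > L) || any(df$end > L))))
            msg <- c(msg, "coordinates must lie in [1, genomeLength]")
        if (is.unsorted(df$start))
            msg <- c(msg, "features must be sorted by start")
    }
    if (length(msg)) msg else TRUE
})

#' BoundaryReport: gene-boundary accounting on the circle
#'
#' For every adjacent feature pair in genomic order (including the pair that
#' wraps the origin), the signed gap in bp: positive gaps are intergenic
#' spacers, negative gaps are overlaps, zero means abutting features. Totals
#' summarise overlap/spacer bp, segment counts and extremes.
#'
#' @slot gaps a \link[S4Vectors]{DataFrame} with columns \code{upstream},
#'   \code{downstream} and \code{gap} (signed bp).
#' @slot totals named list: \code{overlap_total}, \code{overlap_count},
#'   \code{overlap_min}, \code{overlap_max}, \code{spacer_total},
#'   \code{spacer_count}, \code{spacer_min}, \code{spacer_max}
#'   (extremes are \code{NA} when a category is empty).
#'
#' @seealso [computeBoundaries()], [boundaryGaps()], [boundaryTotals()].
#' @exportClass BoundaryReport
setClass("BoundaryReport",
    representation(gaps = "DataFrame", totals = "list"))

setValidity("BoundaryReport", function(object) {
    g <- object@gaps$gap
    t <- object@totals
    ok <- isTRUE(all.equal(sum(g[g > 0]), t$spacer_total)) &&
          isTRUE(all.equal(sum(-g[g < 0]), t$overlap_total)) &&
          sum(g > 0) == t$spacer_count && sum(g < 0) == t$overlap_count
    if (ok) TRUE else "totals are inconsistent with the per-pair gaps"
})

#' @describeIn MitoGenome-class constructor.
#' @param id accession-like identifier.
#' @param seq genome sequence: a \link[Biostrings]{DNAString} or a character
#'   string over A/C/G/T/N.
#' @param circular logical(1).
#' @return a \code{MitoGenome}.
#' @examples
#' g <- MitoGenome("toy", "ACGTACGTAC")
#' genomeLength(g)
#' @export
MitoGenome <- function(id, seq, circular = TRUE) {
    if (is.character(seq)) seq <- Biostrings::DNAString(seq)
    new("MitoGenome", id = as.character(id), seq = seq,
        circular = as.logical(circular))
}

#' @rdname MitoGenome-class
#' @param object,x a \code{MitoGenome}.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname MitoGenome-class
#' @export
setMethod("genomeId", "MitoGenome", function(x) x@id)

#' @rdname MitoGenome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname MitoGenome-class
#' @export
setMethod("genomeSeq", "MitoGenome", function(x) x@seq)

#' @rdname MitoGenome-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname MitoGenome-class
#' @export
setMethod("genomeLength", "MitoGenome", function(x) length(x@seq))

#' @rdname MitoGenome-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname MitoGenome-class
#' @export
setMethod("isCircular", "MitoGenome", function(x) x@circular)

setMethod("show", "MitoGenome", function(object) {
    cat("MitoGenome '", object@id, "': ", length(object@seq), " bp",
        if (object@circular) " (circular)" else " (linear)", "\n", sep = "")
})

#' @rdname GeneTable-class
#' @param x,object a \code{GeneTable}.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname GeneTable-class
#' @export
setMethod("features", "GeneTable", function(x) x@features)

#' @rdname GeneTable-class
#' @export
setMethod("genomeLength", "GeneTable", function(x) x@genomeLength)

#' @rdname GeneTable-class
#' @export
setMethod("length", "GeneTable", function(x) nrow(x@features))

#' Feature lengths on the circle
#'
#' Lengths in bp of every feature of a [GeneTable-class], honouring
#' origin-wrapping features (\code{end < start}).
#'
#' @param x a \code{GeneTable}.
#' @return named integer vector of lengths.
#' @export
featureLengths <- function(x) {
    stopifnot(is(x, "GeneTable"))
    df <- x@features
    len <- ifelse(df$end >= df$start,
                  df$end - df$start + 1L,
                  df$end + x@genomeLength - df$start + 1L)
    stats::setNames(as.integer(len), df$gene)
}

setMethod("show", "GeneTable", function(object) {
    cat("GeneTable: ", nrow(object@features), " features on a ",
        object@genomeLength, " bp circle\n", sep = "")
    k <- table(object@features$kind)
    cat("  ", paste(names(k), k, sep = ": ", collapse = ", "), "\n", sep = "")
})

#' @rdname BoundaryReport-class
#' @param x,object a \code{BoundaryReport}.
#' @export
boundaryGaps <- function(x) {
    stopifnot(is(x, "BoundaryReport"))
    as.data.frame(x@gaps)
}

#' @rdname BoundaryReport-class
#' @export
boundaryTotals <- function(x) {
    stopifnot(is(x, "BoundaryReport"))
    x@totals
}

setMethod("show", "BoundaryReport", function(object) {
    t <- object@totals
    cat("BoundaryReport over ", nrow(object@gaps), " adjacent pairs\n",
        "  overlaps: ", t$overlap_total, " bp in ", t$overlap_count,
        " segments", sep = "")
    if (t$overlap_count > 0)
        cat(" (", t$overlap_min, "-", t$overlap_max, " bp)", sep = "")
    cat("\n  spacers:  ", t$spacer_total, " bp in ", t$spacer_count,
        " spacers", sep = "")
    if (t$spacer_count > 0)
        cat(" (", t$spacer_min, "-", t$spacer_max, " bp)", sep = "")
    cat("\n")
})
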