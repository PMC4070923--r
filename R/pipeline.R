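#' Per-gene class statistics
#'
#' The full degeneracy/divergence summary for one codon-aligned ortholog
#' set: class-wise A+T content (mean and SD across species), class-wise
#' substitution frequency (mean pairwise Jukes-Cantor distance at the
#' class's sites), substitution-count ratios between classes, and the
#' overall Poisson amino-acid distance (ASD) of the translated proteins.
#'
#' @inheritParams classSubstitutionFrequency
#' @param gene label carried into the result row.
#' @return one-row data.frame with columns \code{gene}, \code{AT_0F},
#'   \code{AT_0F_sd}, \code{subst_0F}, (same for 2F and 4F),
#'   \code{R_0F_all}, \code{R_2F_all}, \code{R_4F_all}, \code{ASD}.
#' @export
geneClassStats <- function(orthologSet, gene = "gene",
                           code = geneticCode(),
                           correction = c("JC", "none"),
                           rule = c("concordant", "reference"),
                           reference = 1L) {
    correction <- match.arg(correction)
    rule <- match.arg(rule)
    orthologSet <- unlist(as.list(orthologSet))
    classes <- assignSiteClasses(orthologSet, code, rule, reference)
    comp <- classComposition(orthologSet, code, classes = classes)
    freq <- vapply(c("0", "2", "4"), function(f)
        classSubstitutionFrequency(orthologSet, f, code, correction,
                                   classes = classes)$frequency,
        numeric(1))
    ratios <- tryCatch(classRatios(orthologSet, code, classes = classes),
                       error = function(e) c("0" = NA_real_,
                                             "2" = NA_real_,
                                             "4" = NA_real_))
    prot <- vapply(orthologSet, translateCDS, character(1), code = code)
    asd <- overallASD(prot)$asd
    data.frame(gene = gene,
               AT_0F = comp$at_mean[1], AT_0F_sd = comp$at_sd[1],
               subst_0F = freq[["0"]],
               AT_2F = comp$at_mean[2], AT_2F_sd = comp$at_sd[2],
               subst_2F = freq[["2"]],
               AT_4F = comp$at_mean[3], AT_4F_sd = comp$at_sd[3],
               subst_4F = freq[["4"]],
               R_0F_all = unname(ratios["0"]),
               R_2F_all = unname(ratios["2"]),
               R_4F_all = unname(ratios["4"]),
               ASD = asd)
}

# Column pairs of the standard correlation battery over geneClassStats
# output: class A+T against class substitution frequency, and the
# divergence summaries against each other.
defaultCorrelationPairs <- function() {
    c("AT_0F:subst_0F", "AT_2F:subst_2F", "AT_4F:subst_4F",
      "AT_0F:R_0F_all", "AT_0F:ASD", "R_0F_all:ASD",
      "AT_4F:R_4F_all", "AT_4F:ASD", "R_4F_all:ASD")
}

#' Degeneracy -> divergence -> correlation pipeline
#'
#' Runs [geneClassStats()] on every gene's ortholog set and then the
#' standard correlation battery over the per-gene table: class-wise A+T
#' versus class-wise substitution frequency, and A+T / substitution-ratio /
#' amino-acid-distance cross-correlations.
#'
#' @param orthologSets named list: gene -> named character vector of
#'   codon-aligned CDS (species as names).
#' @param code genetic code from [geneticCode()].
#' @param pairs correlation pairs ("colA:colB"); defaults to the standard
#'   battery.
#' @inheritParams geneClassStats
#' @return list with \code{stats} (gene x statistics data.frame) and
#'   \code{correlations} (data.frame from [correlationBattery()]).
#' @export
runPipeline <- function(orthologSets, code = geneticCode(),
                        pairs = defaultCorrelationPairs(),
                        correction = c("JC", "none"),
                        rule = c("concordant", "reference"),
                        reference = 1L) {
    stats <- do.call(rbind, lapply(names(orthologSets), function(g)
        geneClassStats(orthologSets[[g]], gene = g, code = code,
                       correction = correction, rule = rule,
                       reference = reference)))
    list(stats = stats, correlations = correlationBattery(stats, pairs))
}

#' Write a statistics or correlation table as TSV
#'
#' Numeric columns are written at full precision; the file carries a header
#' comment naming the coordinate/rounding conventions so reports are
#' self-describing.
#'
#' @param x data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeStatsTable <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# mitoComp report; coordinates 1-based inclusive", con)
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
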