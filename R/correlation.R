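#' Pearson correlation with two-tailed significance
#'
#' Sample Pearson r with the two-tailed P value from
#' \code{t = r sqrt((n-2)/(1-r^2))} on n-2 degrees of freedom (the classical
#' test, as implemented by \code{\link[stats]{cor.test}}).
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-zero variance.
#' @param xname,yname labels carried into the result.
#' @return one-row data.frame: \code{var1}, \code{var2}, \code{n}, \code{r},
#'   \code{p}.
#' @examples
#' pearsonCorrelation(1:10, (1:10)^2)
#' @export
pearsonCorrelation <- function(x, y, xname = "x", yname = "y") {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < length(x))
        message(length(x) - sum(ok), " incomplete pair(s) dropped for ",
                xname, " ~ ", yname)
    x <- x[ok]; y <- y[ok]
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in ", if (stats::sd(x) == 0) xname else yname)
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    data.frame(var1 = xname, var2 = yname, n = length(x),
               r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation battery over a per-gene statistics table
#'
#' Runs [pearsonCorrelation()] for a list of named column pairs of a
#' statistics table (rows = genes). Genes with an undefined value in either
#' column of a pair are dropped pairwise.
#'
#' @param table data.frame, or path to a TSV file with a header row.
#' @param pairs character vector of \code{"colA:colB"} pairs, or a list of
#'   2-element character vectors.
#' @return data.frame of [pearsonCorrelation()] rows, one per pair.
#' @examples
#' tsv <- system.file("extdata", "tephritid_gene_stats.tsv",
#'                    package = "mitoComp")
#' correlationBattery(tsv, c("AT_0F:subst_0F", "R_0F_all:ASD"))
#' @export
correlationBattery <- function(table, pairs) {
    if (is.character(table) && length(table) == 1L)
        table <- utils::read.delim(table, comment.char = "#")
    if (is.character(pairs)) pairs <- strsplit(pairs, ":", fixed = TRUE)
    rows <- lapply(pairs, function(pr) {
        if (length(pr) != 2L) stop("each pair must name two columns")
        miss <- setdiff(pr, colnames(table))
        if (length(miss))
            stop("unknown column(s): ", paste(miss, collapse = ", "))
        pearsonCorrelation(table[[pr[1]]], table[[pr[2]]],
                           xname = pr[1], yname = pr[2])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Format a P value the way correlation tables print it
#'
#' Three decimals; values below 0.0005 print as "0.000".
#'
#' @param p numeric vector of P values.
#' @return character vector.
#' @export
formatPValue <- function(p) {
    sprintf("%.3f", roundHalfUp(p, 3))
}
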