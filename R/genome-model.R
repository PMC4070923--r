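#' Read a mitogenome from FASTA
#'
#' Reads the first record of a FASTA file into a [MitoGenome-class]. The
#' record is taken to be the J-strand sequence of a closed circle.
#'
#' @param path FASTA file.
#' @param circular logical(1), default TRUE.
#' @return a \code{MitoGenome}; the record id becomes the genome id.
#' @export
readGenomeFasta <- function(path, circular = TRUE) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("no sequences in ", path)
    id <- sub("\\s.*$", "", names(set)[1])
    MitoGenome(id, set[[1]], circular = circular)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

# Infer feature kind from a gene symbol when the table has no kind column.
inferKind <- function(gene) {
    ifelse(grepl("^trn", gene, ignore.case = TRUE), "tRNA",
    ifelse(grepl("^rrn", gene, ignore.case = TRUE), "rRNA",
    ifelse(toupper(gene) %in% c("CR", "D-LOOP", "DLOOP", "AT-RICH"), "CR",
           "PCG")))
}

#' Read a gene table (TSV dialect)
#'
#' Reads the package's tab-separated annotation dialect: columns \code{gene},
#' \code{strand}, \code{start}, \code{end}, optionally \code{kind},
#' \code{size} and \code{anticodon}. Coordinates are 1-based inclusive on the
#' J strand. Strand tokens \code{F}/\code{R} (as annotation tables are often
#' written) are normalised to \code{J}/\code{N}. If a \code{size} column is
#' present, every declared size must equal the length computed from the
#' coordinates; a mismatch is a hard error naming the offending feature.
#' Lines starting with \code{#} are comments.
#'
#' @param path TSV file.
#' @param genomeLength length of the circle in bp; when \code{NULL}, the
#'   maximum \code{end} coordinate is used.
#' @return a [GeneTable-class] with features sorted by start.
#' @examples
#' tsv <- system.file("extdata", "bminax_gene_table.tsv", package = "mitoComp")
#' gt <- readGeneTable(tsv, genomeLength = 16043)
#' gt
#' @export
readGeneTable <- function(path, genomeLength = NULL) {
    # strand columns of all-F tables must not be read as logicals
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = c(strand = "character",
                                           gene = "character"))
    if (nrow(df) == 0L)
        return(new("GeneTable",
                   features = S4Vectors::DataFrame(
                       gene = character(), strand = character(),
                       start = integer(), end = integer(),
                       kind = character(), anticodon = character()),
                   genomeLength = as.integer(
                       if (is.null(genomeLength)) 1L else genomeLength)))
    need <- c("gene", "strand", "start", "end")
    if (!all(need %in% colnames(df)))
        stop("gene table must have columns ", paste(need, collapse = ", "))
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    if (anyNA(df$start) || anyNA(df$end))
        stop("non-integer coordinates in gene table")
    badTok <- setdiff(unique(df$strand), c("F", "R", "J", "N"))
    if (length(badTok))
        stop("unknown strand token(s): ", paste(badTok, collapse = ", "))
    df$strand <- c(F = "J", R = "N", J = "J", N = "N")[df$strand]
    if (is.null(df$kind)) df$kind <- inferKind(df$gene)
    if (is.null(df$anticodon)) df$anticodon <- NA_character_
    df$anticodon[df$anticodon %in% c("", ".", "-")] <- NA_character_
    if (is.null(genomeLength)) genomeLength <- max(df$end)
    genomeLength <- as.integer(genomeLength)
    out <- sapply(seq_len(nrow(df)), function(i)
        df$start[i] > genomeLength || df$end[i] > genomeLength ||
        df$start[i] < 1L || df$end[i] < 1L)
    if (any(out))
        stop("coordinates outside [1, ", genomeLength, "] for: ",
             paste(df$gene[out], collapse = ", "))
    if (!is.null(df$size)) {
        len <- ifelse(df$end >= df$start, df$end - df$start + 1L,
                      df$end + genomeLength - df$start + 1L)
        bad <- which(as.integer(df$size) != len)
        if (length(bad))
            stop("declared size disagrees with coordinates for: ",
                 paste0(df$gene[bad], " (declared ", df$size[bad],
                        ", computed ", len[bad], ")", collapse = "; "))
    }
    df <- df[order(df$start), , drop = FALSE]
    new("GeneTable",
        features = S4Vectors::DataFrame(
            gene = df$gene, strand = df$strand, start = df$start,
            end = df$end, kind = df$kind, anticodon = df$anticodon),
        genomeLength = genomeLength)
}

#' Write a gene table in the TSV dialect
#'
#' @param gt a [GeneTable-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGeneTable <- function(gt, path) {
    stopifnot(is(gt, "GeneTable"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# coordinates: 1-based inclusive, J-strand",
                 paste0("# genome_length: ", gt@genomeLength)), con)
    df <- as.data.frame(gt@features)
    df$size <- unname(featureLengths(gt))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal reader for locally stored GenBank flat files: parses the ORIGIN
#' sequence and maps \code{CDS}, \code{tRNA}, \code{rRNA} and \code{D-loop}
#' features (with optional \code{complement(...)} locations) onto a
#' [GeneTable-class]. Joined/compound locations are not supported.
#'
#' @param path GenBank flat file.
#' @return list with elements \code{genome} ([MitoGenome-class]) and
#'   \code{genes} ([GeneTable-class]).
#' @export
readGenBank <- function(path) {
    lines <- readLines(path)
    acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
               grep("^ACCESSION", lines, value = TRUE)[1])
    if (is.na(acc)) acc <- "genbank"
    ori <- grep("^ORIGIN", lines)
    if (length(ori) == 0L) stop("no ORIGIN block in ", path)
    seqLines <- lines[(ori[1] + 1L):length(lines)]
    seqLines <- seqLines[!grepl("^//", seqLines)]
    seq <- toupper(gsub("[^a-zA-Z]", "", paste(seqLines, collapse = "")))
    featStart <- grep("^FEATURES", lines)
    if (length(featStart) == 0L) stop("no FEATURES block in ", path)
    block <- lines[(featStart[1] + 1L):(ori[1] - 1L)]
    keyRe <- "^ {5}(\\S+)\\s+(\\S+)\\s*$"
    keys <- grep(keyRe, block)
    kindMap <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                 `D-loop` = "CR")
    rows <- list()
    for (i in seq_along(keys)) {
        key <- sub(keyRe, "\\1", block[keys[i]])
        if (!key %in% names(kindMap)) next
        loc <- sub(keyRe, "\\2", block[keys[i]])
        strand <- if (grepl("^complement\\(", loc)) "N" else "J"
        nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
        if (length(nums) != 2L)
            stop("unsupported location '", loc, "' in ", path)
        to <- if (i < length(keys)) keys[i + 1L] - 1L else length(block)
        quals <- paste(block[keys[i]:to], collapse = " ")
        gene <- sub('.*/gene="([^"]+)".*', "\\1", quals)
        if (gene == quals)
            gene <- sub('.*/product="([^"]+)".*', "\\1", quals)
        if (gene == quals) gene <- if (key == "D-loop") "CR" else key
        rows[[length(rows) + 1L]] <- data.frame(
            gene = gene, strand = strand,
            start = as.integer(nums[1]), end = as.integer(nums[2]),
            kind = unname(kindMap[key]), anticodon = NA_character_,
            stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$start), , drop = FALSE]
    genome <- MitoGenome(acc, seq)
    genes <- new("GeneTable",
                 features = S4Vectors::DataFrame(df),
                 genomeLength = nchar(seq))
    list(genome = genome, genes = genes)
}

#' Overlap and spacer accounting on the circle
#'
#' For each adjacent feature pair in genomic order, including the pair that
#' closes the circle across the origin, computes the signed gap
#' \code{start(next) - end(previous) - 1}: positive values are intergenic
#' spacers, negative values are gene overlaps, zero means abutting. The
#' control region is an ordinary feature, so it creates no artificial gap.
#'
#' Features must be sorted by start and no feature may fully contain another
#' (containment almost always signals a corrupt table and is rejected).
#'
#' @param gt a [GeneTable-class].
#' @return a [BoundaryReport-class].
#' @examples
#' tsv <- system.file("extdata", "bminax_gene_table.tsv", package = "mitoComp")
#' computeBoundaries(readGeneTable(tsv, genomeLength = 16043))
#' @export
computeBoundaries <- function(gt) {
    stopifnot(is(gt, "GeneTable"))
    df <- as.data.frame(gt@features)
    L <- gt@genomeLength
    n <- nrow(df)
    if (n == 0L)
        return(new("BoundaryReport",
                   gaps = S4Vectors::DataFrame(upstream = character(),
                                               downstream = character(),
                                               gap = integer()),
                   totals = gapTotals(integer())))
    if (is.unsorted(df$start)) stop("features must be sorted by start")
    # unwrap origin-spanning features for the containment check
    s <- df$start
    e <- ifelse(df$end >= df$start, df$end, df$end + L)
    for (i in seq_len(n)) {
        inside <- s >= s[i] & e <= e[i]
        inside[i] <- FALSE
        if (any(inside))
            stop("feature '", df$gene[i], "' fully contains '",
                 df$gene[which(inside)[1]], "'")
    }
    if (n == 1L) {
        gap <- as.integer(s[1] + L - e[1] - 1L)
        gaps <- S4Vectors::DataFrame(upstream = df$gene[1],
                                     downstream = df$gene[1], gap = gap)
        return(new("BoundaryReport", gaps = gaps, totals = gapTotals(gap)))
    }
    gap <- c(s[-1] - e[-n] - 1L,           # consecutive pairs
             s[1] + L - e[n] - 1L)         # wrap across the origin
    gaps <- S4Vectors::DataFrame(upstream = df$gene,
                                 downstream = df$gene[c(2:n, 1L)],
                                 gap = as.integer(gap))
    new("BoundaryReport", gaps = gaps, totals = gapTotals(as.integer(gap)))
}

gapTotals <- function(gap) {
    ov <- -gap[gap < 0]
    sp <- gap[gap > 0]
    list(overlap_total = sum(ov), overlap_count = length(ov),
         overlap_min = if (length(ov)) min(ov) else NA_integer_,
         overlap_max = if (length(ov)) max(ov) else NA_integer_,
         spacer_total = sum(sp), spacer_count = length(sp),
         spacer_min = if (length(sp)) min(sp) else NA_integer_,
         spacer_max = if (length(sp)) max(sp) else NA_integer_)
}

#' Extract a feature's coding sequence
#'
#' Returns the J-strand slice for strand \code{J} and its reverse complement
#' for strand \code{N}; a feature with \code{end < start} wraps the origin of
#' the circle.
#'
#' @param genome a [MitoGenome-class].
#' @param start,end 1-based inclusive coordinates.
#' @param strand "J" or "N".
#' @return character(1) sequence, 5'->3' on the coding strand.
#' @examples
#' g <- MitoGenome("toy", "ACGTACGTAC")
#' extractFeatureSequence(g, 1, 4)          # "ACGT"
#' extractFeatureSequence(g, 9, 2)          # wraps: "ACAC"
#' @export
extractFeatureSequence <- function(genome, start, end, strand = c("J", "N")) {
    stopifnot(is(genome, "MitoGenome"))
    strand <- match.arg(strand)
    L <- genomeLength(genome)
    if (start < 1L || start > L || end < 1L || end > L)
        stop("coordinates outside [1, ", L, "]")
    s <- as.character(genome@seq)
    out <- if (end >= start) substr(s, start, end)
           else paste0(substr(s, start, L), substr(s, 1L, end))
    if (strand == "N") out <- revComp(out)
    out
}

#' All feature sequences of an annotated genome
#'
#' @param genome a [MitoGenome-class].
#' @param gt a [GeneTable-class] on the same genome.
#' @return named character vector, one coding-strand sequence per feature.
#' @export
featureSequences <- function(genome, gt) {
    stopifnot(is(gt, "GeneTable"),
              genomeLength(genome) == gt@genomeLength)
    df <- gt@features
    out <- vapply(seq_len(nrow(df)), function(i)
        extractFeatureSequence(genome, df$start[i], df$end[i], df$strand[i]),
        character(1))
    stats::setNames(out, df$gene)
}

#' Start and stop codon summary for protein-coding genes
#'
#' For each CDS: the initiation codon (first 3 nt) and the termination
#' signal. When the trailing 3 nt form a stop codon under the code the stop
#' is complete; otherwise the trailing \code{length mod 3} remainder (1 or
#' 2 nt, a polyadenylation-completed stop) is reported as incomplete. A CDS
#' whose length is a multiple of 3 but does not end in a stop codon is
#' reported with its trailing codon and flagged not complete.
#'
#' @param cdsSet named character vector or list of CDS strings (gene names as
#'   names), each at least 6 nt.
#' @param code genetic code from [geneticCode()].
#' @return data.frame with columns \code{gene}, \code{start_codon},
#'   \code{stop_codon}, \code{stop_complete}.
#' @export
startStopSummary <- function(cdsSet, code = geneticCode()) {
    cdsSet <- unlist(as.list(cdsSet))
    if (any(nchar(cdsSet) < 6L))
        stop("every CDS must be at least 6 nt")
    stops <- stopCodons(code)
    res <- lapply(names(cdsSet), function(g) {
        s <- cdsSet[[g]]
        n <- nchar(s)
        rem <- n %% 3L
        tail3 <- substr(s, n - 2L, n)
        if (rem == 0L) {
            data.frame(gene = g, start_codon = substr(s, 1L, 3L),
                       stop_codon = tail3,
                       stop_complete = tail3 %in% stops)
        } else {
            data.frame(gene = g, start_codon = substr(s, 1L, 3L),
                       stop_codon = substr(s, n - rem + 1L, n),
                       stop_complete = FALSE)
        }
    })
    do.call(rbind, res)
}
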