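# Independent brute-force oracles used to check the package's scanners and
# classifiers. They are deliberately naive: explicit loops and substring
# comparisons, sharing no code with the implementations they check.

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Degeneracy fold by explicit translation of all four alternatives with
# Biostrings::translate (a code path independent of the package's lookup
# table).
oracleFold <- function(codon, position, codeId = "5") {
    gc <- Biostrings::getGeneticCode(as.character(codeId))
    aaOf <- function(cod)
        as.character(Biostrings::translate(
            Biostrings::DNAString(cod),
            genetic.code = gc, no.init.codon = TRUE))
    target <- aaOf(codon)
    n <- 0L
    for (nt in c("A", "C", "G", "T")) {
        alt <- codon
        substr(alt, position, position) <- nt
        if (aaOf(alt) == target) n <- n + 1L
    }
    if (n == 4L) "4" else if (n == 1L) "0" else "2"
}

# All maximal exact tandem arrays (full copies only): one row per (start,
# unit length) with at least minCopies head-to-tail copies, not extendable
# by a full unit on either side.
oracleTandemArrays <- function(seq, minUnit, maxUnit, minCopies) {
    n <- nchar(seq)
    res <- list()
    for (u in minUnit:maxUnit) {
        for (i in seq_len(max(0L, n - 2L * u + 1L))) {
            unit <- substr(seq, i, i + u - 1L)
            k <- 1L
            while (i + (k + 1L) * u - 1L <= n &&
                   substr(seq, i + k * u, i + (k + 1L) * u - 1L) == unit)
                k <- k + 1L
            if (k < minCopies) next
            if (i - u >= 1L &&
                substr(seq, i - u, i - 1L) == unit) next  # not maximal left
            res[[length(res) + 1L]] <-
                data.frame(start = i, end = i + k * u - 1L,
                           unit_length = u, full_copies = k)
        }
    }
    if (!length(res))
        return(data.frame(start = integer(), end = integer(),
                          unit_length = integer(), full_copies = integer()))
    unique(do.call(rbind, res))
}

# Every ungapped alignment window of exactly minLen bp with identity >=
# minIdent, by explicit sliding; subject coordinates on its forward strand.
oracleCounterpartWindows <- function(query, subject, minLen, minIdent) {
    qc <- strsplit(query, "")[[1]]
    res <- list()
    for (st in c("J", "N")) {
        subj <- if (st == "J") subject
                else as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(subject)))
        sc <- strsplit(subj, "")[[1]]
        sn <- length(sc)
        for (qs in seq_len(length(qc) - minLen + 1L)) {
            for (ss in seq_len(sn - minLen + 1L)) {
                id <- sum(qc[qs:(qs + minLen - 1L)] ==
                          sc[ss:(ss + minLen - 1L)])
                if (id / minLen < minIdent) next
                sa <- ss; sb <- ss + minLen - 1L
                if (st == "N") { tmp <- sa; sa <- sn - sb + 1L
                                 sb <- sn - tmp + 1L }
                res[[length(res) + 1L]] <- data.frame(
                    query_start = qs, subject_start = sa, strand = st,
                    identities = id)
            }
        }
    }
    if (!length(res))
        return(data.frame(query_start = integer(),
                          subject_start = integer(), strand = character(),
                          identities = integer()))
    do.call(rbind, res)
}

# All perfect hairpins: maximal Watson-Crick stems of >= minStem pairs
# enclosing a loop with length in loopRange. One row per loop placement.
oracleHairpins <- function(seq, minStem, loopRange) {
    cs <- strsplit(seq, "")[[1]]
    n <- length(cs)
    pair <- function(a, b)
        (a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")
    res <- list()
    for (l in loopRange[1]:loopRange[2]) {
        for (j in seq_len(max(0L, n - l + 1L))) {
            s <- 0L
            while (j - s - 1L >= 1L && j + l + s <= n &&
                   pair(cs[j - s - 1L], cs[j + l + s]))
                s <- s + 1L
            if (s >= minStem)
                res[[length(res) + 1L]] <-
                    data.frame(loop_start = j, loop = l, stem = s)
        }
    }
    if (!length(res))
        return(data.frame(loop_start = integer(), loop = integer(),
                          stem = integer()))
    do.call(rbind, res)
}

# Two-tailed permutation P for a Pearson correlation.
oraclePermutationP <- function(x, y, nPerm = 10000) {
    obs <- abs(cor(x, y))
    hits <- 0L
    for (i in seq_len(nPerm))
        if (abs(cor(x, sample(y))) >= obs - 1e-12) hits <- hits + 1L
    hits / nPerm
}

# Tiny GenBank flat file written from a feature table, for reader tests.
writeToyGenBank <- function(path, seq, feats) {
    ln <- c(sprintf("LOCUS       TOY%21d bp    DNA     circular 01-JAN-2026",
                    nchar(seq)),
            "ACCESSION   TOY001",
            "FEATURES             Location/Qualifiers")
    for (i in seq_len(nrow(feats))) {
        loc <- sprintf("%d..%d", feats$start[i], feats$end[i])
        if (feats$strand[i] == "N")
            loc <- sprintf("complement(%s)", loc)
        ln <- c(ln, sprintf("     %-16s%s", feats$key[i], loc),
                if (!is.na(feats$gene[i]))
                    sprintf('                     /gene="%s"',
                            feats$gene[i]))
    }
    ln <- c(ln, "ORIGIN")
    for (i in seq(1L, nchar(seq), 60L))
        ln <- c(ln, sprintf("%9d %s", i,
                            tolower(substr(seq, i,
                                           min(nchar(seq), i + 59L)))))
    ln <- c(ln, "//")
    writeLines(ln, path)
    path
}
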