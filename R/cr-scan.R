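#' Poly-T stretch finder
#'
#' Maximal runs of T of at least \code{minRun} bp. Both strands are scanned:
#' a run of A on the scanned (J) strand is a poly-T stretch on the N strand.
#' Coordinates are reported on the J strand; \code{genomeStart} shifts local
#' positions into genome coordinates (it is the genome coordinate of the
#' first base of \code{seq}).
#'
#' @param seq DNA string to scan (typically the control region).
#' @param minRun minimum run length, >= 3.
#' @param genomeStart genome coordinate of \code{seq[1]}.
#' @return data.frame with columns \code{kind}, \code{start}, \code{end},
#'   \code{strand}, \code{score} (the run length); zero rows when nothing is
#'   found.
#' @examples
#' findPolyT("AATTTTTTAA", minRun = 5)  # one hit, 3..8, score 6
#' @export
findPolyT <- function(seq, minRun = 5L, genomeStart = 1L) {
    if (minRun < 3L) stop("minRun must be >= 3")
    cs <- chars(toupper(seq))
    hits <- emptyHits()
    for (st in c("J", "N")) {
        base <- if (st == "J") "T" else "A"
        r <- rle(cs == base)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values & r$lengths >= minRun
        if (any(keep))
            hits <- rbind(hits, data.frame(
                kind = "polyT",
                start = starts[keep] + genomeStart - 1L,
                end = ends[keep] + genomeStart - 1L,
                strand = st, score = r$lengths[keep]))
    }
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

emptyHits <- function() {
    data.frame(kind = character(), start = integer(), end = integer(),
               strand = character(), score = numeric())
}

#' TA(A)n-like stretch after a poly-T run
#'
#' Looks downstream of each J-strand poly-T stretch for the longest segment
#' decomposable into TA/TAA units, greedy left to right with ties broken in
#' favour of the longer TAA unit. Segments of fewer than \code{minUnits}
#' units are ignored. The segment must start within \code{windowAfter} bp of
#' the poly-T end but may extend beyond it.
#'
#' @inheritParams findPolyT
#' @param windowAfter search window downstream of each poly-T end, bp.
#' @param minUnits minimum number of TA/TAA units (default 3).
#' @param minRun poly-T minimum run length passed to [findPolyT()].
#' @return data.frame of hits (kind \code{TAAlike}, score = unit count).
#' @export
findTaaStretch <- function(seq, windowAfter = 50L, minUnits = 3L,
                           minRun = 5L, genomeStart = 1L) {
    seq <- toupper(seq)
    pt <- findPolyT(seq, minRun = minRun, genomeStart = 1L)
    pt <- pt[pt$strand == "J", , drop = FALSE]
    hits <- emptyHits()
    n <- nchar(seq)
    for (k in seq_len(nrow(pt))) {
        from <- pt$end[k] + 1L
        to <- min(n, pt$end[k] + windowAfter)
        if (from > to) next
        best <- NULL
        for (i in from:to) {
            dec <- greedyTaaUnits(seq, i, n)
            if (dec$units >= minUnits &&
                (is.null(best) || dec$units > best$units))
                best <- c(dec, start = i)
        }
        if (!is.null(best))
            hits <- rbind(hits, data.frame(
                kind = "TAAlike",
                start = best$start + genomeStart - 1L,
                end = best$start + best$len - 1L + genomeStart - 1L,
                strand = "J", score = best$units))
    }
    hits <- unique(hits)   # nearby poly-T runs can share one stretch
    rownames(hits) <- NULL
    hits
}

# Greedy TA/TAA decomposition starting at position i (prefer TAA).
greedyTaaUnits <- function(seq, i, n) {
    units <- 0L
    pos <- i
    repeat {
        if (pos + 2L <= n && substr(seq, pos, pos + 2L) == "TAA") {
            pos <- pos + 3L
        } else if (pos + 1L <= n && substr(seq, pos, pos + 1L) == "TA") {
            pos <- pos + 2L
        } else break
        units <- units + 1L
    }
    list(units = units, len = pos - i)
}

#' G+A-rich block finder
#'
#' Maximal blocks with purine (G+A) fraction at least \code{minFrac},
#' obtained by merging overlapping qualifying windows of \code{window} bp.
#' The score is the purine fraction of the merged block. This is the scanner
#' used on the context upstream of a control-region poly-T stretch, but it
#' runs on any sequence.
#'
#' @inheritParams findPolyT
#' @param window window size in bp.
#' @param minFrac minimum purine fraction, in (0.5, 1].
#' @return data.frame of hits (kind \code{GArich}, score = purine fraction).
#' @examples
#' findGaRichBlock("GAGAGAGAGA", window = 10, minFrac = 0.9)
#' @export
findGaRichBlock <- function(seq, window = 10L, minFrac = 0.75,
                            genomeStart = 1L) {
    if (minFrac <= 0.5 || minFrac > 1) stop("minFrac must be in (0.5, 1]")
    cs <- chars(toupper(seq))
    n <- length(cs)
    if (n < window) return(emptyHits())
    pur <- as.integer(cs %in% c("G", "A"))
    csum <- c(0L, cumsum(pur))
    wsum <- csum[(window + 1L):(n + 1L)] - csum[1:(n - window + 1L)]
    ok <- which(wsum / window >= minFrac)
    if (!length(ok)) return(emptyHits())
    # merge overlapping qualifying windows into maximal blocks
    grp <- cumsum(c(1L, diff(ok) > window))
    hits <- do.call(rbind, lapply(split(ok, grp), function(idx) {
        a <- min(idx); b <- max(idx) + window - 1L
        data.frame(kind = "GArich", start = a + genomeStart - 1L,
                   end = b + genomeStart - 1L, strand = "J",
                   score = mean(pur[a:b]))
    }))
    rownames(hits) <- NULL
    hits
}

#' Exact tandem repeat finder
#'
#' Exact-match tandem arrays: a unit of \code{minUnit}..\code{maxUnit} bp
#' repeated at least \code{minCopies} times head to tail, maximally extended
#' (including a fractional trailing copy, so copy numbers can be
#' non-integer). Overlapping candidate arrays are collapsed to the
#' highest-copy-number representative (ties: longer span, then leftmost).
#' Mismatch-tolerant repeat detection is deliberately out of scope.
#'
#' @inheritParams findPolyT
#' @param minUnit,maxUnit unit length bounds; \code{maxUnit} defaults to half
#'   the sequence length.
#' @param minCopies minimum number of full copies (>= 2).
#' @return data.frame with columns \code{unit}, \code{unit_length},
#'   \code{copies}, \code{start}, \code{end}.
#' @examples
#' tandemRepeats("ATATATAT", minUnit = 2)  # unit "AT", 4 copies
#' @export
tandemRepeats <- function(seq, minUnit = 2L, maxUnit = NULL,
                          minCopies = 2, genomeStart = 1L) {
    seq <- toupper(seq)
    n <- nchar(seq)
    if (minUnit < 2L) stop("minUnit must be >= 2")
    if (is.null(maxUnit)) maxUnit <- n %/% 2L
    maxUnit <- min(maxUnit, n %/% 2L)
    cand <- list()
    cs <- chars(seq)
    for (u in seq(minUnit, maxUnit)) {
        i <- 1L
        while (i + 2L * u - 1L <= n) {
            # maximality to the left: an array starting one unit earlier is
            # found at that earlier start instead
            if (i > u && substr(seq, i - u, i - 1L) ==
                          substr(seq, i, i + u - 1L)) {
                i <- i + 1L
                next
            }
            unit <- substr(seq, i, i + u - 1L)
            k <- 1L
            while (i + (k + 1L) * u - 1L <= n &&
                   substr(seq, i + k * u, i + (k + 1L) * u - 1L) == unit)
                k <- k + 1L
            if (k >= minCopies) {
                extra <- 0L
                while (i + k * u + extra <= n &&
                       cs[i + k * u + extra] == cs[i + extra %% u])
                    extra <- extra + 1L
                extra <- min(extra, u - 1L)
                cand[[length(cand) + 1L]] <- data.frame(
                    unit = unit, unit_length = u,
                    copies = k + extra / u,
                    start = i, end = i + k * u + extra - 1L,
                    core_end = i + k * u - 1L)
            }
            i <- i + 1L
        }
    }
    if (!length(cand))
        return(data.frame(unit = character(), unit_length = integer(),
                          copies = numeric(), start = integer(),
                          end = integer()))
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$copies, -(cand$end - cand$start),
                       cand$start), , drop = FALSE]
    # collapse on the full-copy core span: a fractional trailing copy must
    # not let an unrelated neighbouring array shadow this one
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        ov <- keep & cand$start <= cand$core_end[i] &
              cand$core_end >= cand$start[i]
        if (!any(ov)) keep[i] <- TRUE
    }
    out <- cand[keep, , drop = FALSE]
    out$core_end <- NULL
    out <- out[order(out$start), , drop = FALSE]
    out$start <- out$start + genomeStart - 1L
    out$end <- out$end + genomeStart - 1L
    rownames(out) <- NULL
    out
}

#' Ungapped counterpart search
#'
#' Slides the query over both strands of the subject at every ungapped
#' offset, scores all alignment windows of \code{minLen} bp, and reports
#' maximal segments whose identity reaches \code{minIdentity} (consecutive
#' qualifying windows of one offset are merged into a single match).
#' Coordinates of N-strand matches are mapped back to the subject's forward
#' strand. Matches are returned best first (percent identity, then length).
#'
#' @param query spacer-like DNA string.
#' @param subject DNA string searched (typically the control region).
#' @param minLen minimum window length, <= query length.
#' @param minIdentity identity threshold in (0, 1]; the default 0.7 reflects
#'   the conservation range typical of spacer counterparts.
#' @param bothStrands scan the reverse complement of the subject too.
#' @param merge merge consecutive qualifying windows of one offset into a
#'   single maximal match (default); \code{FALSE} reports every qualifying
#'   \code{minLen}-bp window individually.
#' @return data.frame with columns \code{query_start}, \code{query_end},
#'   \code{subject_start}, \code{subject_end}, \code{strand}, \code{length},
#'   \code{identities}, \code{percent}.
#' @export
counterpartSearch <- function(query, subject, minLen,
                              minIdentity = 0.7, bothStrands = TRUE,
                              merge = TRUE) {
    query <- toupper(query); subject <- toupper(subject)
    qn <- nchar(query); sn <- nchar(subject)
    if (minLen > qn) stop("minLen exceeds the query length")
    if (minLen < 1L) stop("minLen must be positive")
    qc <- chars(query)
    strands <- if (bothStrands) c("J", "N") else "J"
    out <- list()
    for (st in strands) {
        subj <- if (st == "J") subject else revComp(subject)
        sc <- chars(subj)
        for (off in seq(1L - qn + minLen - 1L, sn - minLen + 1L)) {
            qs <- max(1L, 2L - off)          # first query pos in overlap
            ss <- off + qs - 1L
            ov <- min(qn - qs, sn - ss) + 1L
            if (ov < minLen) next
            m <- qc[qs:(qs + ov - 1L)] == sc[ss:(ss + ov - 1L)]
            csum <- c(0L, cumsum(m))
            w <- csum[(minLen + 1L):(ov + 1L)] - csum[1:(ov - minLen + 1L)]
            ok <- which(w / minLen >= minIdentity)
            if (!length(ok)) next
            grp <- if (merge) cumsum(c(1L, diff(ok) > 1L)) else seq_along(ok)
            for (idx in split(ok, grp)) {
                a <- min(idx); b <- max(idx) + minLen - 1L
                len <- b - a + 1L
                ident <- sum(m[a:b])
                sa <- ss + a - 1L; sb <- ss + b - 1L
                if (st == "N") { tmp <- sa; sa <- sn - sb + 1L
                                 sb <- sn - tmp + 1L }
                out[[length(out) + 1L]] <- data.frame(
                    query_start = qs + a - 1L, query_end = qs + b - 1L,
                    subject_start = sa, subject_end = sb, strand = st,
                    length = len, identities = ident,
                    percent = 100 * ident / len)
            }
        }
    }
    if (!length(out))
        return(data.frame(query_start = integer(), query_end = integer(),
                          subject_start = integer(),
                          subject_end = integer(), strand = character(),
                          length = integer(), identities = integer(),
                          percent = numeric()))
    res <- do.call(rbind, out)
    res <- res[order(-res$percent, -res$length, res$subject_start), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Perfect stem-loop (hairpin) scan
#'
#' All positions where a perfect stem of at least \code{minStem}
#' Watson-Crick pairs (G-U wobble not counted) encloses a loop whose length
#' lies in \code{loopRange}. For each loop placement the stem is extended
#' outward maximally; nested sub-stems of the same placement are not
#' reported separately.
#'
#' @inheritParams findPolyT
#' @param minStem minimum stem length in bp, >= 3.
#' @param loopRange integer length-2 vector, loop length bounds within 3..12.
#' @return data.frame with columns \code{kind}, \code{start}, \code{end},
#'   \code{strand}, \code{score} (stem length) and \code{loop}.
#' @examples
#' hairpinScan("GGGAAAACCC", minStem = 3, loopRange = c(3, 8))
#' @export
hairpinScan <- function(seq, minStem = 3L, loopRange = c(3L, 8L),
                        genomeStart = 1L) {
    if (minStem < 3L) stop("minStem must be >= 3")
    if (loopRange[1] < 3L || loopRange[2] > 12L ||
        loopRange[1] > loopRange[2])
        stop("loopRange must lie within 3..12")
    cs <- chars(toupper(seq))
    n <- length(cs)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    hits <- list()
    for (l in seq(loopRange[1], loopRange[2])) {
        if (n < l + 2L * minStem) next
        for (j in seq_len(n - l + 1L)) {       # loop occupies j .. j+l-1
            s <- 0L
            while (j - s - 1L >= 1L && j + l + s <= n) {
                b1 <- cs[j - s - 1L]; b2 <- cs[j + l + s]
                if (is.na(comp[b1]) || comp[[b1]] != b2) break
                s <- s + 1L
            }
            if (s >= minStem)
                hits[[length(hits) + 1L]] <- data.frame(
                    kind = "hairpin",
                    start = j - s + genomeStart - 1L,
                    end = j + l + s - 1L + genomeStart - 1L,
                    strand = "J", score = s, loop = l)
        }
    }
    if (!length(hits)) {
        e <- emptyHits(); e$loop <- integer()
        return(e)
    }
    out <- do.call(rbind, hits)
    out <- out[order(out$start, out$loop), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export motif/repeat/counterpart hits as BED-like TSV
#'
#' Writes any of the scanner outputs with 1-based inclusive coordinates
#' (the package convention) or, with \code{zeroBased = TRUE}, 0-based
#' half-open coordinates as in BED.
#'
#' @param hits a data.frame with \code{start} and \code{end} columns.
#' @param path output file.
#' @param zeroBased write 0-based half-open coordinates.
#' @return invisibly, `path`.
#' @export
writeBedLike <- function(hits, path, zeroBased = FALSE) {
    out <- hits
    if (zeroBased) out$start <- out$start - 1L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# coordinates: ",
                      if (zeroBased) "0-based half-open"
                      else "1-based inclusive"), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
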