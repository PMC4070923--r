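test_that("poly-T runs are maximal and scanned on both strands", {
    h <- findPolyT("AATTTTTTAA", minRun = 5)
    tRun <- h[h$strand == "J", ]
    expect_equal(nrow(tRun), 1L)
    expect_equal(c(tRun$start, tRun$end, tRun$score), c(3, 8, 6))
    expect_equal(nrow(findPolyT("ACACAC", minRun = 3)), 0L)
    # A-runs are N-strand poly-T
    hA <- findPolyT("CCAAAAACC", minRun = 5)
    expect_equal(hA$strand, "N")
    # genome-coordinate reporting
    hg <- findPolyT("AATTTTTTAA", minRun = 5, genomeStart = 101)
    expect_equal(hg$start[hg$strand == "J"], 103)
    expect_error(findPolyT("TTTT", minRun = 2), "minRun")
})

test_that("TA(A)n stretches decompose greedily after a poly-T", {
    h <- findTaaStretch("TTTTTGTATATAA", windowAfter = 10, minRun = 5)
    expect_equal(nrow(h), 1L)
    expect_equal(h$score, 3)            # TA + TA + TAA
    expect_equal(c(h$start, h$end), c(7, 13))
    # nothing decomposable downstream
    expect_equal(nrow(findTaaStretch("TTTTTCCCCCC", minRun = 5)), 0L)
    # unit count invariant to trailing non-TA characters
    h2 <- findTaaStretch("TTTTTGTATATAAGGGG", windowAfter = 10,
                         minRun = 5)
    expect_equal(h2$score, 3)
})

test_that("purine-rich blocks are maximal merged windows", {
    h <- findGaRichBlock("GAGAGAGAGA", window = 10, minFrac = 0.9)
    expect_equal(nrow(h), 1L)
    expect_equal(h$score, 1.0)
    expect_equal(nrow(findGaRichBlock("CTCTCTCTCT", window = 10,
                                      minFrac = 0.9)), 0L)
    # 20 bp context with 16 purines -> fraction 0.8 reported
    ctx <- paste0(paste(rep("GA", 8), collapse = ""), "CTCT")
    h2 <- findGaRichBlock(ctx, window = 20, minFrac = 0.75)
    expect_equal(h2$score, 0.8)
    expect_error(findGaRichBlock("GAGA", window = 2, minFrac = 0.4),
                 "minFrac")
})

test_that("exact tandem repeats are found with fractional extension", {
    r <- tandemRepeats("ATATATAT", minUnit = 2)
    expect_equal(nrow(r), 1L)
    expect_equal(r$unit, "AT")
    expect_equal(r$copies, 4)
    expect_equal(nrow(tandemRepeats("GATTACA", minUnit = 2)), 0L)
    # the published CR repeat pattern: a 15-mer head-to-tail three times
    s <- paste0("GG", strrep("CCTTTTAAATTTTCC", 3), "GG")
    r2 <- tandemRepeats(s, minUnit = 4, maxUnit = 20)
    hit <- r2[r2$unit == "CCTTTTAAATTTTCC", ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$copies, 3)
    expect_equal(c(hit$start, hit$end), c(3, 47))
    # fractional trailing copy: span = round(unit_length * copies)
    r3 <- tandemRepeats("CCGACCGACC", minUnit = 3, maxUnit = 4)
    expect_equal(r3$unit, "CCGA")
    expect_equal(r3$copies, 2.5)
    expect_equal(r3$end - r3$start + 1, round(r3$unit_length * r3$copies))
})

test_that("tandem repeats agree with the brute-force oracle", {
    set.seed(41)
    for (i in 1:25) {
        s <- randomSeq(200, letters = c("A", "T", "G", "C"))
        got <- tandemRepeats(s, minUnit = 2, maxUnit = 6, minCopies = 2)
        want <- oracleTandemArrays(s, 2, 6, 2)
        # every reported repeat verifies structurally against the string
        for (k in seq_len(nrow(got))) {
            u <- got$unit_length[k]
            span <- substr(s, got$start[k], got$end[k])
            expect_equal(substr(span, 1, u), got$unit[k])
            expect_equal(span,
                         substr(strrep(got$unit[k],
                                       ceiling(got$copies[k]) + 1),
                                1, nchar(span)))
            expect_gte(got$copies[k], 2)
        }
        # every oracle array is represented: covered by a reported repeat
        # with at least as many copies
        for (k in seq_len(nrow(want)))
            expect_true(any(got$start <= want$end[k] &
                            got$end >= want$start[k] &
                            got$copies >= want$full_copies[k]),
                        label = paste("oracle array", i, k))
    }
})

test_that("counterpart windows agree with the naive slider", {
    set.seed(43)
    for (i in 1:25) {
        q <- randomSeq(30)
        s <- randomSeq(200)
        got <- counterpartSearch(q, s, minLen = 12, minIdentity = 0.7,
                                 merge = FALSE)
        want <- oracleCounterpartWindows(q, s, 12, 0.7)
        key <- function(d) sort(paste(d$query_start, d$subject_start,
                                      d$strand, d$identities))
        expect_equal(key(got), key(want), label = paste("seq", i))
    }
})

test_that("counterpart search finds planted and reverse-strand matches", {
    set.seed(47)
    cr <- randomSeq(300)
    q <- substr(cr, 101, 115)
    top <- counterpartSearch(q, cr, minLen = 15)[1, ]
    expect_equal(top$percent, 100)
    expect_equal(c(top$subject_start, top$subject_end), c(101, 115))
    # pure-A query vs pure-T subject matches on the N strand
    topN <- counterpartSearch("AAAAA", "TTTTT", minLen = 5)[1, ]
    expect_equal(topN$strand, "N")
    expect_equal(topN$percent, 100)
    # 23 identities over a 33 bp window -> 69.7%
    a <- randomSeq(33)
    b <- a
    flip <- sample(33, 10)
    for (j in flip) {
        cur <- substr(b, j, j)
        substr(b, j, j) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    m <- counterpartSearch(a, b, minLen = 33, minIdentity = 0.5,
                           bothStrands = FALSE)[1, ]
    expect_equal(m$identities, 23L)
    expect_equal(roundHalfUp(m$percent, 1), 69.7)
    expect_error(counterpartSearch("AAA", "AAAA", minLen = 5), "minLen")
})

test_that("hairpin scan agrees with the brute-force oracle", {
    h <- hairpinScan("GGGAAAACCC", minStem = 3, loopRange = c(3, 8))
    expect_equal(nrow(h), 1L)
    expect_equal(c(h$start, h$end, h$score, h$loop), c(1, 10, 3, 4))
    expect_equal(nrow(hairpinScan("AAAAAAAAAA", 3, c(3, 8))), 0L)
    set.seed(53)
    for (i in 1:25) {
        s <- randomSeq(200)
        got <- hairpinScan(s, minStem = 3, loopRange = c(3, 6))
        want <- oracleHairpins(s, 3, c(3, 6))
        key <- function(st, lp, sc) sort(paste(st, lp, sc))
        expect_equal(key(got$start + got$score, got$loop, got$score),
                     key(want$loop_start, want$loop, want$stem),
                     label = paste("seq", i))
        # hairpin count is invariant under reverse complement
        expect_equal(nrow(hairpinScan(revComp(s), 3, c(3, 6))), nrow(got))
    }
})

test_that("scanners are pure and BED-like export round-trips", {
    set.seed(59)
    s <- randomSeq(150)
    expect_identical(findPolyT(s), findPolyT(s))
    expect_identical(tandemRepeats(s, 2, 6), tandemRepeats(s, 2, 6))
    hits <- findPolyT(paste0(s, "TTTTTTT"), minRun = 5)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeBedLike(hits, tmp)
    back <- utils::read.delim(tmp, comment.char = "#")
    expect_equal(back$start, hits$start)
    writeBedLike(hits, tmp, zeroBased = TRUE)
    back0 <- utils::read.delim(tmp, comment.char = "#")
    expect_equal(back0$start, hits$start - 1L)
})
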