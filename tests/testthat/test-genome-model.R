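table2 <- system.file("extdata", "bminax_gene_table.tsv",
                      package = "mitoComp")

test_that("gene table parsing normalises strands and validates sizes", {
    gt <- readGeneTable(table2, genomeLength = 16043)
    expect_s4_class(gt, "GeneTable")
    expect_equal(length(gt), 38L)
    df <- as.data.frame(features(gt))
    expect_true(all(df$strand %in% c("J", "N")))
    expect_equal(df$strand[df$gene == "trnI"], "J")   # F -> J
    expect_equal(df$strand[df$gene == "trnQ"], "N")   # R -> N
    expect_equal(unname(featureLengths(gt)["trnI"]), 65L)
    expect_equal(unname(featureLengths(gt)["CR"]), 1141L)
    expect_false(is.unsorted(df$start))

    # declared-size mismatch is a hard error naming the feature
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tstrand\tstart\tend\tsize",
                 "trnX\tF\t1\t65\t66"), tmp)
    expect_error(readGeneTable(tmp, 100), "trnX")

    # unknown strand token
    writeLines(c("gene\tstrand\tstart\tend", "g\t+\t1\t10"), tmp)
    expect_error(readGeneTable(tmp, 100), "strand token")

    # coordinate outside the genome
    writeLines(c("gene\tstrand\tstart\tend", "g\tF\t5\t200"), tmp)
    expect_error(readGeneTable(tmp, 100), "outside")

    # empty table -> empty feature list
    writeLines("gene\tstrand\tstart\tend", tmp)
    expect_equal(length(readGeneTable(tmp, 100)), 0L)
})

test_that("origin-wrapping feature lengths are computed on the circle", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tstrand\tstart\tend", "g\tF\t9\t3"), tmp)
    gt <- readGeneTable(tmp, genomeLength = 10)
    expect_equal(unname(featureLengths(gt)), 5L)  # positions 9,10,1,2,3
})

test_that("boundary accounting reproduces the annotated overlaps/spacers", {
    gt <- readGeneTable(table2, genomeLength = 16043)
    rep <- computeBoundaries(gt)
    g <- boundaryGaps(rep)
    expect_equal(g$gap[g$upstream == "nad4"], -17L)
    expect_equal(g$gap[g$upstream == "trnC"], 42L)
    t <- boundaryTotals(rep)
    expect_equal(t$overlap_total, 43L)
    expect_equal(t$overlap_count, 12L)
    expect_equal(t$spacer_total, 178L)
    expect_equal(t$spacer_count, 16L)
    # a fully annotated circle closes exactly
    expect_equal(sum(featureLengths(gt)) + sum(g$gap), 16043L)
})

test_that("boundary accounting rejects bad input and handles one feature", {
    mk <- function(df, L) new("GeneTable",
        features = S4Vectors::DataFrame(df, anticodon = NA_character_),
        genomeLength = as.integer(L))
    one <- mk(data.frame(gene = "CR", strand = "J", start = 1L,
                         end = 100L, kind = "CR"), 100)
    t <- boundaryTotals(computeBoundaries(one))
    expect_equal(t$spacer_count + t$overlap_count, 0L)  # whole circle

    cont <- mk(data.frame(gene = c("a", "b"), strand = "J",
                          start = c(1L, 5L), end = c(50L, 20L),
                          kind = "PCG"), 100)
    expect_error(computeBoundaries(cont), "contains")
})

test_that("feature sequence extraction honours strand and origin wrap", {
    g <- MitoGenome("toy", "ACGTACGTAC")
    expect_equal(extractFeatureSequence(g, 1, 4, "J"), "ACGT")
    expect_equal(extractFeatureSequence(g, 1, 4, "N"), "ACGT")  # palindrome
    expect_equal(extractFeatureSequence(g, 9, 2, "J"), "ACAC")
    # revcomp twice is the identity for arbitrary features
    set.seed(7)
    g2 <- MitoGenome("r", randomSeq(60))
    for (i in 1:10) {
        a <- sort(sample(60, 2))
        j <- extractFeatureSequence(g2, a[1], a[2], "J")
        n <- extractFeatureSequence(g2, a[1], a[2], "N")
        expect_equal(revComp(n), j)
    }
    expect_error(extractFeatureSequence(g, 0, 4), "outside")
})

test_that("start/stop summary distinguishes complete and truncated stops", {
    res <- startStopSummary(c(g1 = "ATGAAATAA",     # complete TAA
                              g2 = "GTCAAAAAAT",    # incomplete "T"
                              g3 = "TCGAAAAAA"))    # no stop at all
    expect_equal(res$start_codon, c("ATG", "GTC", "TCG"))
    expect_equal(res$stop_codon[1], "TAA")
    expect_true(res$stop_complete[1])
    expect_equal(res$stop_codon[2], "T")
    expect_false(res$stop_complete[2])
    expect_false(res$stop_complete[3])
    expect_error(startStopSummary(c(g = "ATGAA")), "at least 6")
})

test_that("the GenBank reader maps features onto the gene table", {
    set.seed(11)
    seq <- randomSeq(300)
    tmp <- withr::local_tempfile(fileext = ".gb")
    writeToyGenBank(tmp, seq, data.frame(
        key = c("tRNA", "CDS", "rRNA", "D-loop"),
        start = c(1L, 70L, 150L, 230L), end = c(65L, 140L, 220L, 300L),
        strand = c("J", "N", "J", "J"),
        gene = c("trnI", "nad2", "rrnS", NA)))
    got <- readGenBank(tmp)
    expect_equal(genomeLength(got$genome), 300L)
    expect_equal(as.character(genomeSeq(got$genome)), seq)
    df <- as.data.frame(features(got$genes))
    expect_equal(df$gene[1:3], c("trnI", "nad2", "rrnS"))
    expect_equal(df$kind, c("tRNA", "PCG", "rRNA", "CR"))
    expect_equal(df$strand, c("J", "N", "J", "J"))
    # CDS sequence extracted from the parsed genome is the N-strand revcomp
    expect_equal(extractFeatureSequence(got$genome, 70, 140, "N"),
                 revComp(substr(seq, 70, 140)))
})

test_that("gene tables round-trip through the TSV writer", {
    gt <- readGeneTable(table2, genomeLength = 16043)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeGeneTable(gt, tmp)
    back <- readGeneTable(tmp, genomeLength = 16043)
    expect_equal(as.data.frame(features(back)),
                 as.data.frame(features(gt)))
})
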