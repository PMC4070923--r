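test_that("simulated genomes reproduce the planted boundary totals", {
    cfg <- simulationConfig(seed = 5)
    sim <- simulateGenome(cfg)
    t <- boundaryTotals(computeBoundaries(sim$genes))
    expect_equal(t$overlap_total, sim$truth$overlap_total)
    expect_equal(t$overlap_count, sim$truth$overlap_count)
    expect_equal(t$spacer_total, sim$truth$spacer_total)
    expect_equal(t$spacer_count, sim$truth$spacer_count)
    expect_equal(genomeLength(sim$genome), sim$truth$genome_length)

    # planting overlaps {8, 17} and spacers {42, 10} gives 25/2 and 52/2
    cfg2 <- simulationConfig(seed = 6,
        layout = data.frame(gene = c("a", "b", "c", "d", "CR"),
                            len = c(300L, 300L, 300L, 300L, 1141L),
                            strand = "J",
                            kind = c("PCG", "PCG", "PCG", "PCG", "CR")),
        gaps = c(-8L, -17L, 42L, 10L, 0L), counterpartLen = 0L)
    t2 <- boundaryTotals(computeBoundaries(simulateGenome(cfg2)$genes))
    expect_equal(t2$overlap_total, 25L)
    expect_equal(t2$overlap_count, 2L)
    expect_equal(t2$spacer_total, 52L)
    expect_equal(t2$spacer_count, 2L)
})

test_that("a gene-less configuration yields a bare control region", {
    cfg <- simulationConfig(seed = 7,
        layout = data.frame(gene = character(), len = integer(),
                            strand = character(), kind = character()),
        gaps = integer(0), counterpartLen = 0L)
    sim <- simulateGenome(cfg)
    expect_equal(length(sim$genes), 1L)
    expect_equal(features(sim$genes)$kind, "CR")
    t <- boundaryTotals(computeBoundaries(sim$genes))
    expect_equal(t$overlap_count + t$spacer_count, 0L)
})

test_that("planted control-region motifs are recovered at their coordinates", {
    cfg <- simulationConfig(seed = 8)
    sim <- simulateGenome(cfg)
    tr <- sim$truth
    crSeq <- extractFeatureSequence(sim$genome, tr$cr_start, tr$cr_end)

    pt <- findPolyT(crSeq, minRun = 10, genomeStart = tr$cr_start)
    expect_true(any(pt$start == tr$polyT[1] & pt$end == tr$polyT[2] &
                    pt$strand == "J"))

    taa <- findTaaStretch(crSeq, windowAfter = 50, minRun = 10,
                          genomeStart = tr$cr_start)
    expect_true(any(taa$start == tr$taa[1] & taa$end == tr$taa[2]))

    ga <- findGaRichBlock(crSeq, window = 10, minFrac = 0.9,
                          genomeStart = tr$cr_start)
    expect_true(any(ga$start <= tr$gaRich[1] & ga$end >= tr$gaRich[2]))

    td <- tandemRepeats(crSeq, minUnit = 10, maxUnit = 20,
                        genomeStart = tr$cr_start)
    expect_true(any(td$unit == tr$tandem$unit &
                    td$start == tr$tandem$start &
                    td$copies >= tr$tandem$copies))

    spacer <- extractFeatureSequence(sim$genome,
                                     tr$counterpart$spacer_start,
                                     tr$counterpart$spacer_end)
    hits <- counterpartSearch(spacer, crSeq, minLen = nchar(spacer))
    expect_equal(hits$percent[1], 100)
    expect_true(any(hits$percent == 100 &
                    hits$subject_start + tr$cr_start - 1L ==
                        tr$counterpart$cr_start))
})

test_that("the generator is deterministic in its seed", {
    a <- simulateGenome(simulationConfig(seed = 11))
    b <- simulateGenome(simulationConfig(seed = 11))
    expect_identical(as.character(genomeSeq(a$genome)),
                     as.character(genomeSeq(b$genome)))
    expect_identical(a$truth, b$truth)
    cfg <- simulationConfig(seed = 11)
    o1 <- simulateOrthologSet(cfg, "cox1")
    o2 <- simulateOrthologSet(cfg, "cox1")
    expect_identical(o1$sequences, o2$sequences)
    # different genes draw independent streams
    o3 <- simulateOrthologSet(cfg, "nad2")
    expect_false(identical(o1$root, o3$root))
})

test_that("zero rates leave every species identical to the root", {
    cfg <- simulationConfig(seed = 12, nSpecies = 4L,
                            genes = data.frame(gene = "g", codons = 100L),
                            rates = c("0" = 0, "2" = 0, "4" = 0))
    o <- simulateOrthologSet(cfg, "g")
    expect_true(all(o$sequences == o$root))
    for (f in c("0", "2", "4")) {
        r <- classSubstitutionFrequency(o$sequences, f)
        if (!is.na(r$frequency)) expect_equal(r$frequency, 0)
    }
})

test_that("sequences stay translatable and honour the A+T bias ordering", {
    cfg <- simulationConfig(seed = 13, nSpecies = 6L,
                            genes = data.frame(gene = "g", codons = 300L))
    o <- simulateOrthologSet(cfg, "g")
    stops <- stopCodons(geneticCode("5"))
    for (s in o$sequences) {
        cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
        expect_false(any(cods %in% stops))
    }
    # classes with higher configured A+T bias show higher observed A+T
    # (checked between the weakly and moderately evolved classes; heavy
    # substitution under the symmetric kernel erodes root bias toward 50%)
    cc <- classComposition(o$sequences)
    expect_true(cc$at_mean[cc$fold == "2"] > cc$at_mean[cc$fold == "0"])
    rootAT <- vapply(c("0", "2", "4"), function(k)
        mean(chartr("ACGT", "1001",
                    strsplit(o$root, "")[[1]][o$truth$siteClass == k])
             == "1"), numeric(1))
    expect_true(rootAT[["4"]] > rootAT[["0"]])
})

test_that("a planted bias-rate coupling across genes surfaces as positive r", {
    # genes whose 4-fold A+T bias rises with their 4-fold rate: the
    # downstream correlation between AT_4F and subst_4F must come out
    # positive (rates kept modest so root bias survives evolution)
    nGene <- 8L
    bias4 <- seq(0.50, 0.92, length.out = nGene)
    rate4 <- seq(0.02, 0.35, length.out = nGene)
    rows <- lapply(seq_len(nGene), function(i) {
        cfg <- simulationConfig(seed = 600L + i, nSpecies = 8L,
            genes = data.frame(gene = "g", codons = 400L),
            rates = c("0" = 0.01, "2" = 0.05, "4" = rate4[i]),
            atBias = c("0" = 0.6, "2" = 0.7, "4" = bias4[i]))
        o <- simulateOrthologSet(cfg, "g")
        cls <- assignSiteClasses(o$sequences)
        cc <- classComposition(o$sequences, classes = cls)
        data.frame(
            AT_4F = cc$at_mean[cc$fold == "4"],
            subst_4F = classSubstitutionFrequency(
                o$sequences, "4", classes = cls)$frequency)
    })
    tab <- do.call(rbind, rows)
    expect_gt(pearsonCorrelation(tab$AT_4F, tab$subst_4F)$r, 0)
})

test_that("extreme rate contrasts are recovered downstream", {
    # rates (0, 0, high): the 4-fold frequency dominates
    cfg <- simulationConfig(seed = 14, nSpecies = 6L,
                            genes = data.frame(gene = "g", codons = 300L),
                            rates = c("0" = 0, "2" = 0, "4" = 0.5))
    o <- simulateOrthologSet(cfg, "g")
    cls <- assignSiteClasses(o$sequences)
    f0 <- classSubstitutionFrequency(o$sequences, "0", classes = cls)
    f4 <- classSubstitutionFrequency(o$sequences, "4", classes = cls)
    expect_equal(f0$frequency, 0)
    expect_gt(f4$frequency, 0.5)
})
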