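#' Simulation configuration
#'
#' Bundles everything the synthetic-data generator needs: a circular-genome
#' layout with planted overlaps/spacers and a control region carrying planted
#' motifs, and an ortholog-evolution model with independently controlled
#' substitution rates and A+T biases per degeneracy class.
#'
#' The defaults emulate a ten-taxon tephritid-like study: 10 species, the 13
#' mitochondrial protein-coding genes at their typical sizes, per-class
#' expected substitution rates 0.02 / 0.2 / 0.8 per site (0-, 2-, 4-fold)
#' with A+T biases 0.66 / 0.78 / 0.79, and a ~1.1 kb control region with a
#' 24 bp poly-T stretch, a TA(A)n stretch, a purine-rich block and an exact
#' tandem repeat.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param nSpecies number of species evolved from the common root.
#' @param genes data.frame with columns \code{gene} and \code{codons}
#'   (codon count per gene) used by [simulateOrthologSet()].
#' @param rates named numeric, expected substitutions per site on each tip
#'   branch for classes "0", "2", "4".
#' @param atBias named numeric in [0,1], target A+T bias per class.
#' @param layout data.frame with columns \code{gene}, \code{len} (bp),
#'   \code{strand} (J/N), \code{kind}, used by [simulateGenome()].
#' @param gaps integer vector, the signed gap planted after each layout
#'   feature (the last entry closes the circle back to the first feature).
#' @param crLength control-region length in bp.
#' @param crPolyT planted poly-T run length.
#' @param crTandemUnit,crTandemCopies planted exact tandem repeat.
#' @param counterpartLen length of the spacer slice copied into the CR (the
#'   planted spacer counterpart); 0 disables.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nSpecies = 10L,
                             genes = data.frame(
                                 gene = c("nad2", "cox1", "cox2", "atp8",
                                          "atp6", "cox3", "nad3", "nad6",
                                          "cob", "nad1", "nad4l", "nad4",
                                          "nad5"),
                                 codons = c(340L, 511L, 228L, 53L, 225L,
                                            263L, 117L, 173L, 378L, 313L,
                                            98L, 446L, 573L)),
                             rates = c("0" = 0.02, "2" = 0.2, "4" = 0.8),
                             atBias = c("0" = 0.66, "2" = 0.78,
                                        "4" = 0.79),
                             layout = data.frame(
                                 gene = c("trnI", "nad2", "trnW", "cox1",
                                          "trnC", "nad5", "nad4", "rrnS",
                                          "CR"),
                                 len = c(65L, 1023L, 68L, 1536L, 62L,
                                         1720L, 1341L, 782L, 1141L),
                                 strand = c("J", "J", "J", "J", "N", "N",
                                            "N", "N", "J"),
                                 kind = c("tRNA", "PCG", "tRNA", "PCG",
                                          "tRNA", "PCG", "PCG", "rRNA",
                                          "CR")),
                             gaps = c(0L, -1L, 8L, -8L, 42L, 0L, -17L,
                                      0L, 0L),
                             crLength = 1141L,
                             crPolyT = 24L,
                             crTandemUnit = "CCTTTTAAATTTTCC",
                             crTandemCopies = 3L,
                             counterpartLen = 15L) {
    stopifnot(all(rates >= 0), all(atBias >= 0 & atBias <= 1),
              nrow(layout) == length(gaps), crLength >= 200L,
              crPolyT + nchar(crTandemUnit) * crTandemCopies +
                  counterpartLen + 80L <= crLength)
    cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
                genes = genes, rates = rates, atBias = atBias,
                layout = layout, gaps = as.integer(gaps),
                crLength = as.integer(crLength),
                crPolyT = as.integer(crPolyT),
                crTandemUnit = toupper(crTandemUnit),
                crTandemCopies = as.integer(crTandemCopies),
                counterpartLen = as.integer(counterpartLen))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate an annotated circular genome
#'
#' Lays the configured features head to tail around a circle with the
#' planted signed gaps (negative = overlap), fills the sequence with random
#' A+T-biased DNA, and assembles a control region containing a planted
#' poly-T run, a TA(A)n stretch downstream of it, a purine-rich block
#' upstream of it, an exact tandem repeat and (optionally) a copy of a
#' spacer slice, all at recorded coordinates. Guard bases around each
#' planted motif keep it maximal at exactly the recorded positions.
#'
#' @param cfg a [simulationConfig()].
#' @return list with \code{genome} ([MitoGenome-class]), \code{genes}
#'   ([GeneTable-class]) and \code{truth}: planted overlap/spacer totals and
#'   motif coordinates (genome coordinates, 1-based inclusive).
#' @export
simulateGenome <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    lay <- cfg$layout
    n <- nrow(lay)
    if (n == 0L) {
        lay <- data.frame(gene = "CR", len = cfg$crLength, strand = "J",
                          kind = "CR")
        cfg$gaps <- 0L
        n <- 1L
    }
    lay$len[lay$kind == "CR"] <- cfg$crLength
    start <- integer(n); end <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
        start[i] <- pos
        end[i] <- pos + lay$len[i] - 1L
        pos <- end[i] + 1L + cfg$gaps[i]
    }
    L <- sum(lay$len) + sum(cfg$gaps)
    if (any(end > L) || any(start < 1L))
        stop("planted features exceed the genome length")
    geno <- chars(randomDNA(L, at = 0.67))
    crIdx <- which(lay$kind == "CR")[1]
    truth <- list(
        genome_length = L,
        overlap_total = sum(-cfg$gaps[cfg$gaps < 0]),
        overlap_count = sum(cfg$gaps < 0),
        spacer_total = sum(cfg$gaps[cfg$gaps > 0]),
        spacer_count = sum(cfg$gaps > 0))
    if (!is.na(crIdx)) {
        cr <- buildCR(cfg)
        geno[start[crIdx]:end[crIdx]] <- cr$chars
        off <- start[crIdx] - 1L
        truth$cr_start <- start[crIdx]
        truth$cr_end <- end[crIdx]
        truth$polyT <- cr$polyT + off
        truth$taa <- cr$taa + off
        truth$gaRich <- cr$gaRich + off
        truth$tandem <- list(unit = cfg$crTandemUnit,
                             copies = cfg$crTandemCopies,
                             start = cr$tandem[1] + off,
                             end = cr$tandem[2] + off)
        if (cfg$counterpartLen > 0L) {
            sp <- which(cfg$gaps >= cfg$counterpartLen)[1]
            if (!is.na(sp)) {
                qs <- end[sp] + 1L
                qe <- qs + cfg$counterpartLen - 1L
                geno[qs:qe] <- geno[(cr$counterpart[1] + off):
                                    (cr$counterpart[2] + off)]
                truth$counterpart <- list(
                    spacer_start = qs, spacer_end = qe,
                    cr_start = cr$counterpart[1] + off,
                    cr_end = cr$counterpart[2] + off)
            }
        }
    }
    genome <- MitoGenome(paste0("sim", cfg$seed),
                         paste(geno, collapse = ""))
    genes <- new("GeneTable",
                 features = S4Vectors::DataFrame(
                     gene = lay$gene, strand = lay$strand,
                     start = start, end = end, kind = lay$kind,
                     anticodon = NA_character_),
                 genomeLength = L)
    validObject(genes)
    list(genome = genome, genes = genes, truth = truth)
}

# Assemble the CR with planted motifs at fixed local offsets; returns the
# character vector plus local (1-based) coordinates of each planted motif.
buildCR <- function(cfg) {
    L <- cfg$crLength
    cs <- chars(randomDNA(L, at = 0.78))
    # purine-rich block at 41..60, guarded by pyrimidines
    ga <- chars(paste(sample(c("G", "A"), 20L, replace = TRUE),
                      collapse = ""))
    cs[41:60] <- ga
    cs[40] <- "C"; cs[61] <- "C"
    # poly-T run right after a guard base
    ptStart <- 70L
    ptEnd <- ptStart + cfg$crPolyT - 1L
    cs[ptStart:ptEnd] <- "T"
    cs[ptStart - 1L] <- "G"; cs[ptEnd + 1L] <- "G"
    # TA(A)n stretch ~10 bp downstream of the poly-T
    taaStart <- ptEnd + 10L
    units <- c("TAA", "TA", "TAA", "TA", "TAA", "TAA")
    taa <- chars(paste(units, collapse = ""))
    cs[taaStart:(taaStart + length(taa) - 1L)] <- taa
    cs[taaStart - 1L] <- "C"
    cs[taaStart + length(taa)] <- "C"
    # exact tandem repeat in the middle of the CR
    unit <- chars(cfg$crTandemUnit)
    arr <- rep(unit, cfg$crTandemCopies)
    tdStart <- taaStart + length(taa) + 30L
    tdEnd <- tdStart + length(arr) - 1L
    cs[tdStart:tdEnd] <- arr
    cs[tdStart - 1L] <- "G"; cs[tdEnd + 1L] <- "G"
    # counterpart source segment near the 3' end
    cpStart <- tdEnd + 20L
    cpEnd <- cpStart + max(cfg$counterpartLen, 1L) - 1L
    if (cpEnd >= L)
        stop("planted CR motifs exceed the declared CR length")
    list(chars = cs,
         polyT = c(ptStart, ptEnd),
         taa = c(taaStart, taaStart + length(taa) - 1L),
         gaRich = c(41L, 60L),
         tandem = c(tdStart, tdEnd),
         counterpart = c(cpStart, cpEnd))
}

#' Simulate a codon-aligned ortholog set with known class rates
#'
#' Draws a root CDS whose codons are sampled with per-class A+T bias (the
#' probability of each sense codon is the product, over its three positions,
#' of a class-conditional nucleotide distribution: A and T share the class's
#' A+T bias equally, G and C share the remainder), then evolves each species
#' independently from the root (star phylogeny). Each site receives a
#' Poisson-distributed number of substitutions at its class rate; every
#' substitution replaces the base with one of the other three uniformly,
#' redrawn if the codon would become a stop, so all sequences stay
#' translatable. On a star, the expected pairwise divergence at a class is
#' twice the class rate, which keeps parameter-recovery checks analytic.
#'
#' @param cfg a [simulationConfig()].
#' @param gene gene name from \code{cfg$genes}.
#' @return list with \code{sequences} (named character vector, species ->
#'   CDS, codon-aligned by construction), \code{root} and \code{truth}
#'   (per-class rates, A+T biases and the per-site class vector of the
#'   root).
#' @export
simulateOrthologSet <- function(cfg, gene) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    gi <- match(gene, cfg$genes$gene)
    if (is.na(gi)) stop("gene '", gene, "' is not in the configuration")
    set.seed((cfg$seed * 1009L + gi * 9973L) %% .Machine$integer.max)
    nCodons <- cfg$genes$codons[gi]
    code <- geneticCode("5")
    sense <- senseCodons(code)
    ft <- foldTable(code)
    w <- vapply(sense, function(cod) {
        prod(vapply(1:3, function(p) {
            cls <- ft[cod, p]
            bias <- cfg$atBias[[cls]]
            if (substr(cod, p, p) %in% c("A", "T")) bias / 2
            else (1 - bias) / 2
        }, numeric(1)))
    }, numeric(1))
    if (all(w == 0)) stop("no sense codon satisfies the A+T bias")
    rootCodons <- sample(sense, nCodons, replace = TRUE, prob = w)
    siteClass <- as.vector(t(ft[rootCodons, , drop = FALSE]))
    siteRate <- cfg$rates[siteClass]
    nts <- c("A", "C", "G", "T")
    stops <- stopCodons(code)
    evolveOne <- function() {
        cod <- rootCodons
        nSub <- stats::rpois(length(siteRate), siteRate)
        for (s in which(nSub > 0L)) {
            ci <- (s - 1L) %/% 3L + 1L
            p <- (s - 1L) %% 3L + 1L
            for (h in seq_len(nSub[s])) {
                cur <- substr(cod[ci], p, p)
                repeat {
                    newNt <- sample(setdiff(nts, cur), 1L)
                    cand <- cod[ci]
                    substr(cand, p, p) <- newNt
                    if (!cand %in% stops) break
                }
                cod[ci] <- cand
            }
        }
        paste(cod, collapse = "")
    }
    seqs <- vapply(seq_len(cfg$nSpecies), function(i) evolveOne(),
                   character(1))
    names(seqs) <- paste0("sp", seq_len(cfg$nSpecies))
    list(sequences = seqs,
         root = paste(rootCodons, collapse = ""),
         truth = list(rates = cfg$rates, atBias = cfg$atBias,
                      siteClass = siteClass))
}
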