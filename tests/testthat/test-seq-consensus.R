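test_that("consensus calling applies coverage and noise thresholds", {
    m <- siteCounts(c(9, 0, 0, 0),     # coverage 9 -> masked
                    c(60, 0, 40, 0),   # minor 0.40 > 0.35 -> het R
                    c(70, 0, 30, 0),   # minor 0.30 <= 0.35 -> majority A
                    c(0, 50, 50, 0),   # 50/50 -> het S
                    c(35, 0, 0, 65))   # minor 0.35, not > 0.35 -> majority T
    expect_equal(callConsensus(m), "NRAST")
    ## frequency-based above the coverage floor: scaling counts at
    ## called sites leaves calls unchanged
    expect_equal(callConsensus(m[-1, ] * 10), callConsensus(m[-1, ]))
    ## exactly at the boundary: 0.35 is not > 0.35
    expect_equal(callConsensus(siteCounts(c(65, 35, 0, 0))), "A")
    ## three-way tie for the major allele
    expect_warning(out <- callConsensus(siteCounts(c(10, 10, 10, 0))),
                   "three-way tie")
    expect_equal(out, "N")
})

test_that("all six two-base ambiguity codes are reachable", {
    pairs <- list(M = c(50, 50, 0, 0), R = c(50, 0, 50, 0),
                  W = c(50, 0, 0, 50), S = c(0, 50, 50, 0),
                  Y = c(0, 50, 0, 50), K = c(0, 0, 50, 50))
    for (code in names(pairs))
        expect_equal(callConsensus(siteCounts(pairs[[code]])), code)
})

test_that("translation expands heterozygous codons and masks Ns", {
    expect_equal(translateCds("ATGGCT")$protein, "MA")
    expect_equal(translateCds("ATR")$states[[1]], c("I", "M"))
    expect_equal(translateCds("ANT")$protein, "X")
    expect_error(translateCds("ATGG"), "divisible by 3")
    expect_warning(w <- translateCds("ATGTAAGCT"), "internal stop")
    expect_true(w$internalStop)
    expect_equal(w$protein, "M*A")
})

test_that("unambiguous translation agrees with Biostrings", {
    set.seed(20)
    for (i in 1:10) {
        cds <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                     collapse = "")
        ref <- as.character(Biostrings::translate(
            Biostrings::DNAString(cds), no.init.codon = TRUE))
        expect_equal(suppressWarnings(translateCds(cds)$protein), ref)
    }
})

test_that("within-species variable sites follow the pooling rule", {
    tr <- function(cds) suppressWarnings(translateCds(cds)$states)
    ## four conspecific individuals, two populations
    base <- "ATGGCTTCA"                  # M A S
    het <- "ATGGCTKCA"                   # site 3: TCA/GCA -> A/S
    sub <- "ATGGCTGCA"                   # M A A
    sameAll <- variableSitesWithinSpecies(
        list(tr(base), tr(base), tr(base), tr(base)),
        species = rep("spA", 4), population = rep(c("p1", "p2"), 2))
    expect_equal(nrow(sameAll), 0)

    withHet <- variableSitesWithinSpecies(
        list(tr(base), tr(het), tr(base), tr(base)),
        species = rep("spA", 4), population = rep(c("p1", "p2"), 2),
        gene = "lws")
    expect_equal(withHet$codon_index, 3)
    expect_equal(withHet$states, "A/S")

    ## variation across populations within the species is pooled
    acrossPop <- variableSitesWithinSpecies(
        list(tr(base), tr(base), tr(sub), tr(sub)),
        species = rep("spA", 4), population = rep(c("p1", "p2"), each = 2))
    expect_equal(acrossPop$codon_index, 3)

    ## different species never pool
    between <- variableSitesWithinSpecies(
        list(tr(base), tr(base), tr(sub), tr(sub)),
        species = rep(c("spA", "spB"), each = 2),
        population = rep(c("p1", "p2"), each = 2))
    expect_equal(nrow(between), 0)
})

test_that("planted variants are recovered from synthetic pileups", {
    ref <- "ATGGCTTCAGGATTCCTG"
    alt <- sub("TCA", "GCA", ref)        # codon 3 S -> A
    ## spA: one het individual, one hom-ref; spB: both hom-ref
    pu <- list(
        a1 = generatePileup(ref, alt, coverage = 60, errorRate = 0,
                            seed = 301),
        a2 = generatePileup(ref, ref, coverage = 60, errorRate = 0,
                            seed = 302),
        b1 = generatePileup(ref, ref, coverage = 60, errorRate = 0,
                            seed = 303),
        b2 = generatePileup(ref, ref, coverage = 60, errorRate = 0,
                            seed = 304))
    cons <- lapply(pu, callConsensus)
    trs <- lapply(cons, function(s) suppressWarnings(translateCds(s)$states))
    rep <- variableSitesWithinSpecies(
        trs, species = c("spA", "spA", "spB", "spB"),
        population = c("p1", "p2", "p1", "p2"), gene = "lws")
    ## exactly the planted site, in the species carrying both states
    expect_equal(rep$species, "spA")
    expect_equal(rep$codon_index, 3)
    expect_equal(rep$states, "A/S")
})

test_that("variable sites imply nucleotide-level consensus differences", {
    set.seed(17)
    ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    seqs <- list()
    for (i in 1:4) {
        alt <- strsplit(ref, "")[[1]]
        pos <- sample(60, 2)
        alt[pos] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
        seqs[[i]] <- callConsensus(generatePileup(
            ref, paste(alt, collapse = ""), coverage = 80,
            errorRate = 0.001, seed = 400 + i))
    }
    trs <- lapply(seqs, function(s) suppressWarnings(translateCds(s)$states))
    rep <- variableSitesWithinSpecies(trs, species = rep("sp", 4),
                                      population = rep("p", 4))
    if (nrow(rep)) {
        for (pos in rep$codon_index) {
            nt <- vapply(seqs, substr, "", 3 * pos - 2, 3 * pos)
            expect_true(length(unique(nt)) > 1 ||
                            any(grepl("[MRWSYK]", nt)))
        }
    }
    expect_true(TRUE)
})

test_that("bovine RH1 mapping is a flagged table lookup", {
    idMap <- data.frame(codon_index = 1:10, rh1_position = 1:10)
    got <- mapToBovineRh1(c(2, 5), idMap)
    expect_equal(got$rh1_position, c(2, 5))
    offMap <- data.frame(codon_index = 1:10, rh1_position = 4:13)
    expect_equal(mapToBovineRh1(c(1, 7), offMap)$rh1_position, c(4, 10))
    un <- mapToBovineRh1(c(3, 99), offMap)
    expect_equal(un$mapped, c(TRUE, FALSE))
    expect_equal(un$rh1_position[2], 99)
    expect_error(mapToBovineRh1(1, data.frame(x = 1)), "offset map")
})

test_that("pileup reader validates contiguity", {
    df <- data.frame(gene = "lws", position = c(1, 2, 3),
                     A = c(10, 0, 0), C = c(0, 10, 0),
                     G = c(0, 0, 10), T = c(0, 0, 0))
    path <- writeTmpTsv(df, "pu.tsv")
    got <- readPileup(path)
    expect_equal(nrow(got), 3)
    df$position[3] <- 5
    expect_error(readPileup(writeTmpTsv(df, "pu2.tsv")), "contiguous")
})
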