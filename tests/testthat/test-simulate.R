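test_that("simulated genomes honor block GC and are seed-deterministic", {
    cfg <- simConfig(chromLengths = c(c1 = 1e5),
                     blockGCRange = c(0.5, 0.5), seed = 71)
    g <- simulateGenome(cfg)
    gc <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
    se <- sqrt(0.5 * 0.5 / 1e5)
    expect_lt(abs(gc - 0.5), 3 * se)
    g2 <- simulateGenome(cfg)
    expect_identical(as.character(g), as.character(g2))
})

test_that("duplicated segments lose k-mer uniqueness on both copies", {
    cfg <- simConfig(chromLengths = c(c1 = 4e4),
                     duplications = list(list(chrom = "c1", start = 1000,
                                              length = 5000,
                                              targetChrom = "c1",
                                              targetStart = 20000)),
                     seed = 72)
    g <- simulateGenome(cfg)
    tr <- computeUniquePositions(g, k = 50)
    ## interior of both copies is non-unique; flanks stay unique
    expect_false(any(tr@flags$c1[1000:5950]))
    expect_false(any(tr@flags$c1[20000:24950]))
    expect_true(mean(tr@flags$c1[30000:35000]) > 0.99)

    bad <- simConfig(chromLengths = c(c1 = 4e4),
                     duplications = list(list(chrom = "c1", start = 39000,
                                              length = 5000,
                                              targetChrom = "c1",
                                              targetStart = 1)),
                     seed = 72)
    expect_error(simulateGenome(bad), "out of bounds")
})

test_that("euploid fragment shares follow the weight field", {
    cfg <- simConfig(chromLengths = c(c1 = 2e5, c2 = 1e5, c21 = 5e4),
                     nFragments = 2e5, gcWindow = 60L,
                     fetalFraction = 0, seed = 73)
    g <- simulateGenome(cfg)
    sim <- simulateFragments(g, cfg)
    counts <- as.numeric(sim$truth$perChromCounts[names(g)])
    share <- counts / sum(counts)
    expected <- sim$truth$expectedShare[names(g)]
    se <- sqrt(expected * (1 - expected) / sum(counts))
    expect_true(all(abs(share - expected) < 4 * se))
    expect_equal(sim$truth$expectedRepresentation, 1)
})

test_that("trisomy at fetal fraction 0.2 lifts the target by 1 + f/2", {
    cfg <- simConfig(chromLengths = c(c1 = 2e6, c2 = 1.5e6, c3 = 1.4e6,
                                      c21 = 1e5),
                     nFragments = 1e6, gcWindow = 60L,
                     fetalFraction = 0.2, trisomy = "c21", seed = 74)
    g <- simulateGenome(cfg)
    w <- samplingWeights(g, cfg)
    sim <- simulateFragments(g, cfg, weights = w)
    ## euploid-expected share of c21, from the same weight field with
    ## the copy factor removed
    tot <- w$cells$total
    totEu <- tot / w$cells$copy
    shareEu <- sum(totEu[w$cells$chrom == "c21"]) / sum(totEu)
    n21 <- as.numeric(sim$truth$perChromCounts[["c21"]])
    N <- sum(sim$truth$perChromCounts)
    ratio <- (n21 / N) / shareEu
    se <- sqrt(shareEu * (1 - shareEu) / N) / shareEu
    expect_lt(abs(ratio - 1.10), 3 * se)
    expect_equal(sim$truth$expectedRepresentation, 1.10)
})

test_that("uniform rates and unit motif weights give uniform starts", {
    cfg <- simConfig(chromLengths = c(c1 = 1e6),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = NULL, nFragments = 2e4,
                     gcWindow = 60L, fetalFraction = 0, seed = 75)
    g <- simulateGenome(cfg)
    w <- samplingWeights(g, cfg)
    notRejected <- vapply(1:100, function(i) {
        sim <- simulateFragments(g, cfg, seed = 75 + i, weights = w)
        p5 <- plasmaBias:::.fivePrimeEnds(sim$fragments)
        ## support excludes only the few context-less edge positions
        ks <- suppressWarnings(
            ks.test(p5, "punif", 3, 1e6 - 2))
        ks$p.value >= 0.01
    }, logical(1))
    expect_gte(mean(notRejected), 0.95)
})

test_that("realized motif frequencies converge to the weight-implied law", {
    cfg <- simConfig(chromLengths = c(c1 = 1e6),
                     blockGCRange = c(0.5, 0.5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     nFragments = 1e6, gcWindow = 60L,
                     fetalFraction = 0, seed = 76)
    g <- simulateGenome(cfg)
    sim <- simulateFragments(g, cfg)
    tab <- motifTable(sim$fragments, g, mapqMin = NA)
    obs <- rowSums(tab@counts) / sum(tab@counts)
    ## implied law: base-composition frequency of each 3-mer times its
    ## cleavage weight, renormalized (uniform base composition here)
    w <- rep(1, 64)
    names(w) <- breakpointMotifs()
    w[names(cfg$motifWeights)] <- cfg$motifWeights
    implied <- w / 64
    implied <- implied / sum(implied)
    expect_lt(0.5 * sum(abs(obs - implied)), 0.01)
})

test_that("fragment lengths follow the nucleosomal mixture", {
    cfg <- simConfig(chromLengths = c(c1 = 5e5), nFragments = 5e4,
                     fetalFraction = 0, seed = 77)
    g <- simulateGenome(cfg)
    sim <- simulateFragments(g, cfg)
    len <- GenomicRanges::width(sim$fragments)
    ## interior fragments only (ends truncate at chromosome edges)
    interior <- GenomicRanges::start(sim$fragments) > 500 &
        GenomicRanges::end(sim$fragments) < 5e5 - 500
    len <- len[interior]
    expect_lt(abs(mean(len < 250) - 0.85), 0.01)
    expect_lt(abs(mean(len[len < 250]) - 166), 1)
    expect_lt(abs(mean(len[len >= 250]) - 340), 2)
    expect_true(all(len >= 50))
})

test_that("simulation outputs round-trip through FASTA/BED/JSON", {
    cfg <- simConfig(chromLengths = c(c1 = 5e4), nFragments = 500,
                     fetalFraction = 0, seed = 78)
    g <- simulateGenome(cfg)
    sim <- simulateFragments(g, cfg)
    dir <- tempfile()
    writeSimulation(g, sim$fragments, sim$truth, dir)
    g2 <- loadFasta(file.path(dir, "genome.fa"))
    expect_identical(as.character(g2), as.character(g))
    fr2 <- readFragments(file.path(dir, "fragments.bed"))
    expect_equal(length(fr2), length(sim$fragments))
    expect_equal(GenomicRanges::start(fr2),
                 GenomicRanges::start(sim$fragments))
    expect_equal(as.character(GenomicRanges::strand(fr2)),
                 as.character(GenomicRanges::strand(sim$fragments)))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    expect_equal(truth$expectedRepresentation, 1)
})
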