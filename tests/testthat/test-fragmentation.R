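test_that("breakpoint 3-mers classify exactly 64 contexts", {
    m <- breakpointMotifs()
    expect_length(m, 64L)
    expect_false(anyDuplicated(m) > 0)
    expect_true(all(grepl("^[ACGT]\\*[ACGT][ACGT]$", m)))
})

test_that("motif extraction hand-walks the toy reference", {
    g <- toyGenome(c(c1 = "AACCCCGT"))
    ## + strand fragment with 5' end at 0-based 3 (1-based 4):
    ## offsets -2/0/+1 read bases A (pos 2), C (pos 4), C (pos 5)
    frPlus <- makeFragments("c1", 4, 6, strand = "+")
    tabPlus <- motifTable(frPlus, g, mapqMin = NA)
    expect_equal(tabPlus@counts["A*CC", "plus"], 1L)
    expect_equal(sum(tabPlus@counts), 1L)

    ## - strand fragment with 5' end at 0-based 5 (1-based 6):
    ## complemented context gives A/G/G
    frMinus <- makeFragments("c1", 4, 6, strand = "-")
    tabMinus <- motifTable(frMinus, g, mapqMin = NA)
    expect_equal(tabMinus@counts["A*GG", "minus"], 1L)

    ## context leaving the chromosome is excluded and counted
    frEdge <- makeFragments("c1", 1, 3, strand = "+")
    tabEdge <- motifTable(frEdge, g, mapqMin = NA)
    expect_equal(sum(tabEdge@counts), 0L)
    expect_equal(unname(tabEdge@excluded["plus"]), 1L)
})

test_that("base profiles are flat for an unbiased generator", {
    cfg <- simConfig(chromLengths = c(c1 = 3e5),
                     blockGCRange = c(0.5, 0.5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = NULL, nFragments = 4e4,
                     fetalFraction = 0, seed = 41)
    g <- simulateGenome(cfg)
    sim <- simulateFragments(g, cfg)
    prof <- baseProfile(sim$fragments, g, end = "5p")
    expect_true(all(abs(rowSums(prof@proportions) - 1) < 1e-9))
    se <- sqrt(0.25 * 0.75 / min(prof@counts))
    expect_true(all(abs(prof@proportions - 0.25) < 4 * se))

    ## strand-symmetric null: the 3' profile mirrors the 5' profile as
    ## reverse complement within sampling error
    prof3 <- baseProfile(sim$fragments, g, end = "3p")
    mirrored <- prof3@proportions[rev(seq_along(prof3@offsets)),
                                  c("T", "G", "C", "A")]
    expect_true(all(abs(prof@proportions - mirrored) < 8 * se))
})

test_that("cleavage weights elevate C exactly at offsets -2, 0, +1", {
    cfg <- simConfig(chromLengths = c(c1 = 3e5),
                     blockGCRange = c(0.5, 0.5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = c("C*CC" = 50), nFragments = 4e4,
                     fetalFraction = 0, seed = 43)
    g <- simulateGenome(cfg)
    sim <- simulateFragments(g, cfg)
    prof <- baseProfile(sim$fragments, g, end = "5p")
    cProp <- prof@proportions[, "C"]
    biased <- prof@offsets %in% c(-2L, 0L, 1L)
    expect_true(all(cProp[biased] > 0.45))
    expect_true(all(abs(cProp[!biased] - 0.25) < 0.03))
})

test_that("positional TV singles out the biased offset", {
    ## bias only at offset -2: all motifs with C at -2 share the weight
    w <- rep(8, 16)
    names(w) <- grep("^C\\*", breakpointMotifs(), value = TRUE)
    cfg <- simConfig(chromLengths = c(c1 = 3e5),
                     blockGCRange = c(0.5, 0.5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = w, nFragments = 1e5,
                     fetalFraction = 0, seed = 45)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    cands <- c(-6L, -2L, 0L, 1L, 4L)
    tv <- vapply(cands, function(o)
        positionalTV(sim$fragments, g, tr, candidate = o,
                     nPositions = 4e4, seed = 46), numeric(1))
    expect_equal(cands[which.max(tv)], -2L)
    expect_gt(max(tv), 3 * max(tv[cands != -2L]))
})

test_that("greedy selection recovers the motif offsets and stops on null", {
    cfg <- simConfig(chromLengths = c(c1 = 3e5),
                     blockGCRange = c(0.5, 0.5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = c("C*CC" = 40), nFragments = 1e5,
                     fetalFraction = 0, seed = 47)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    sel <- greedyMotifPositions(sim$fragments, g, tr,
                                candidates = -10:10, maxK = 3L,
                                nPositions = 3e4, seed = 48)
    expect_setequal(sel$offsets, c(-2L, 0L, 1L))

    sel1 <- greedyMotifPositions(sim$fragments, g, tr,
                                 candidates = -10:10, maxK = 1L,
                                 nPositions = 3e4, seed = 48)
    expect_length(sel1$offsets, 1L)
    expect_true(sel1$offsets %in% c(-2L, 0L, 1L))

    ## null generator: sample densely so the TV noise floor sits well
    ## below the 0.005 gain tolerance
    cfg0 <- simConfig(chromLengths = c(c1 = 3e5),
                      blockGCRange = c(0.5, 0.5),
                      rateCurve = list(peak = 0.45, concentration = 0),
                      motifWeights = NULL, nFragments = 1e6,
                      fetalFraction = 0, seed = 49)
    g0 <- simulateGenome(cfg0)
    sim0 <- simulateFragments(g0, cfg0)
    sel0 <- greedyMotifPositions(sim0$fragments, g0,
                                 allUniqueTrack(g0, 50),
                                 candidates = -10:10, maxK = 3L,
                                 gainTol = 0.005,
                                 nPositions = 1e6, seed = 50)
    expect_length(sel0$offsets, 0L)
})

test_that("strand homogeneity test matches the textbook chi-square", {
    counts <- matrix(0L, 64, 2,
                     dimnames = list(breakpointMotifs(),
                                     c("plus", "minus")))
    set.seed(51)
    counts[, 1] <- rpois(64, 200)
    counts[, 2] <- counts[, 1]
    tab <- new("MotifFrequencyTable", counts = counts,
               excluded = c(plus = 0L, minus = 0L))
    res <- strandHomogeneityTest(tab)
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)
    expect_equal(res$df, 20)

    ## direct sum((O - E)^2 / E) oracle on perturbed counts
    counts[, 2] <- rpois(64, 200)
    tab2 <- new("MotifFrequencyTable", counts = counts,
                excluded = c(plus = 0L, minus = 0L))
    res2 <- strandHomogeneityTest(tab2)
    o <- motifTopTable(tab2, 20)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(res2$statistic, sum((o - e)^2 / e))
})

test_that("strand homogeneity keeps its nominal type-I error", {
    set.seed(52)
    p <- as.numeric(rdirichlet1 <- {x <- rgamma(64, 2); x / sum(x)})
    reject <- vapply(1:200, function(i) {
        counts <- cbind(plus = rmultinom(1, 1e5, p)[, 1],
                        minus = rmultinom(1, 1e5, p)[, 1])
        rownames(counts) <- breakpointMotifs()
        tab <- new("MotifFrequencyTable", counts = counts,
                   excluded = c(plus = 0L, minus = 0L))
        strandHomogeneityTest(tab)$p.value < 0.05
    }, logical(1))
    expect_gt(mean(reject), 0.01)
    expect_lt(mean(reject), 0.10)
})

test_that("stratum weights are proportions and assignment is positional", {
    g <- toyGenome(c(c1 = "AACCCCGTAACCCCGT"))
    fr <- makeFragments("c1", c(4, 4), c(6, 6), strand = c("+", "-"))
    a <- assignStrata(fr, g, motifs = c("A*CC"))
    ## + fragment has motif A*CC (stratum 1); - fragment C*GT... not in set
    expect_equal(a@stratum[1], 1L)
    expect_equal(a@stratum[2], 2L)
    expect_equal(sum(a@weights), 1)
})

test_that("stratified correction with the full motif set reproduces the single-position correction", {
    cfg <- simConfig(chromLengths = c(c1 = 4e5), nFragments = 1e5,
                     gcWindow = 60L, fetalFraction = 0, seed = 53)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    bt <- addBinAnnotation(assignBins(sim$fragments, binScheme(g, 20000)),
                           g, tr)
    st <- singlePositionFit(sim$fragments, g, tr, l = 60,
                            sampleSize = 2e5, seed = 54)
    ref <- singlePositionCorrect(bt, st, g, tr)
    a <- assignStrata(sim$fragments, g, motifs = breakpointMotifs())
    expect_equal(a@weights, c(1, 0))
    out <- stratifiedCorrect(bt, sim$fragments, g, tr, a, l = 60,
                             sampleSize = 2e5, seed = 54)
    expect_equal(correctedCounts(out, "singlepos_frag"),
                 correctedCounts(ref, "singlepos"), tolerance = 1e-12)
})

test_that("stratified correction matches unstratified under identical GC curves", {
    cfg <- simConfig(chromLengths = c(c1 = 8e5), nFragments = 4e5,
                     motifWeights = NULL, gcWindow = 60L,
                     fetalFraction = 0, seed = 55)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    bt <- addBinAnnotation(assignBins(sim$fragments, binScheme(g, 40000)),
                           g, tr)
    st <- singlePositionFit(sim$fragments, g, tr, l = 60,
                            sampleSize = 4e5, seed = 56)
    ref <- singlePositionCorrect(bt, st, g, tr)
    a <- assignStrata(sim$fragments, g)
    out <- stratifiedCorrect(bt, sim$fragments, g, tr, a, l = 60,
                             sampleSize = 4e5, seed = 56)
    r <- correctedCounts(out, "singlepos_frag") /
        correctedCounts(ref, "singlepos")
    expect_true(all(abs(r - 1) < 0.02))
})
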