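## BinTable built directly from vectors, for tests that exercise the
## models rather than the binning
makeBinTable <- function(counts, gc, chrom = "c1", binSize = 1000L,
                         mappability = NULL, valid = TRUE) {
    n <- length(counts)
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start = (seq_len(n) - 1L) * binSize + 1L,
                                width = binSize))
    S4Vectors::mcols(gr)$raw_count <- counts
    S4Vectors::mcols(gr)$analysis <- TRUE
    S4Vectors::mcols(gr)$gc <- gc
    S4Vectors::mcols(gr)$valid <- rep_len(valid, n)
    if (!is.null(mappability))
        S4Vectors::mcols(gr)$mappability <- mappability
    new("BinTable", bins = gr, binSize = binSize, dropped = 0L)
}

test_that("tvScore evaluates the half-L1 distance", {
    expect_equal(tvScore(c(50, 50), c(7, 7)), 0)      # constant rate
    expect_equal(tvScore(c(50, 50), c(9, 0)), 0.5)    # all mass in one
    expect_equal(tvScore(c(10, 30, 60), c(5, 10, 5)), 0.35)
    expect_error(tvScore(c(10, 10), c(0, 0)), "fragments")
    expect_error(tvScore(c(0, 0), c(1, 1)), "positions")
})

test_that("tvScore is bounded, relabel-invariant and refinement-monotone", {
    set.seed(31)
    for (rep in 1:20) {
        nFine <- sample(6:24, 1)
        n <- rpois(nFine, 40) + 1
        F <- rpois(nFine, 8)
        if (sum(F) == 0) F[1] <- 1
        tvFine <- tvScore(n, F)
        expect_gte(tvFine, 0)
        expect_lte(tvFine, 1)
        ## relabeling
        perm <- sample(nFine)
        expect_equal(tvScore(n[perm], F[perm]), tvFine)
        ## coarsen by random merging: TV can only drop
        groups <- sort(sample(1:3, nFine, replace = TRUE))
        nC <- tapply(n, groups, sum)
        FC <- tapply(F, groups, sum)
        expect_lte(tvScore(as.numeric(nC), as.numeric(FC)),
                   tvFine + 1e-12)
    }
})

test_that("LOESS correction is exact on flat signal and near-exact on a line", {
    gc <- seq(0.30, 0.60, length.out = 120)
    flat <- makeBinTable(rep(40, 120), gc)
    res <- loessGCCorrect(flat)
    expect_equal(correctedCounts(res$bins, "loess"), rep(1, 120),
                 tolerance = 1e-6)

    lin <- makeBinTable(100 + 300 * gc, gc)
    res2 <- loessGCCorrect(lin)
    expect_true(all(abs(correctedCounts(res2$bins, "loess") - 1) < 0.01))
})

test_that("zero-count bins are excluded from the fit but still corrected", {
    gc <- seq(0.30, 0.60, length.out = 60)
    counts <- rep(50, 60)
    counts[10] <- 0
    bt <- makeBinTable(counts, gc)
    res <- loessGCCorrect(bt)
    corr <- correctedCounts(res$bins, "loess")
    expect_equal(corr[10], 0)
    expect_equal(corr[-10], rep(1, 59), tolerance = 1e-6)
    expect_gt(res$fit@predictions[10], 0)
})

test_that("LOESS correction refuses degenerate GC coverage", {
    bt <- makeBinTable(rep(40, 10), rep(c(0.40, 0.41), 5))
    expect_error(loessGCCorrect(bt), "occupied GC intervals")
})

test_that("GC window selection takes the peak, or 180 bp when flat", {
    mk <- function(scores, lengths = seq_along(scores))
        new("TVScoreCurve", windowLengths = as.integer(lengths),
            scores = scores, selected = NA_integer_)
    peaked <- mk(0.02 + 0.03 * exp(-(1:700 - 150)^2 / 2000))
    expect_equal(selectGCWindow(peaked)@selected, 150L)
    flat <- mk(rep(0.02, 700))
    expect_equal(selectGCWindow(flat)@selected, 180L)
    ## motif spike below 10 bp only: outside the eligible range
    spiked <- mk(c(rep(0.02, 700)) + c(0, 0, 0, 0.12, rep(0, 696)))
    expect_equal(selectGCWindow(spiked)@selected, 180L)
})

test_that("single-position fit recovers a flat rate", {
    cfg <- simConfig(chromLengths = c(c1 = 4e5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = NULL, nFragments = 2e5,
                     gcWindow = 60L, fetalFraction = 0, seed = 5)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    st <- singlePositionFit(sim$fragments, g, tr, l = 60,
                            sampleSize = 3e5, seed = 6)
    well <- st@strata$n >= 500
    r <- 2e5 / (2 * 4e5)   # fragments per (position, strand)
    expect_true(all(abs(st@strata$smooth[well] / r - 1) < 0.10))
})

test_that("single-position fit recovers a Beta-shaped GC rate curve", {
    cfg <- simConfig(chromLengths = c(c1 = 1e6),
                     rateCurve = list(peak = 0.45, concentration = 30),
                     motifWeights = NULL, nFragments = 3e5,
                     gcWindow = 100L, fetalFraction = 0, seed = 8)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    st <- singlePositionFit(sim$fragments, g, tr, l = 100,
                            sampleSize = 5e5, seed = 9)
    well <- st@strata$n >= 200
    truth <- dbeta(st@strata$gc[well] / 100, 1 + 0.45 * 30,
                   1 + 0.55 * 30)
    expect_gte(cor(st@strata$smooth[well], truth), 0.95)
})

test_that("aggregated predictions match a position-by-position oracle", {
    g <- randomGenome(c(c1 = 3000), seed = 13, gc = 0.5)
    k <- 25L
    tr <- computeUniquePositions(g, k)
    scheme <- binScheme(g, 1000)
    l <- 40L
    smoothAll <- seq(0.1, 1, length.out = l + 1)  # hand-set rate curve
    st <- new("GCStrataTable", windowLength = l,
              strata = data.frame(gc = 0:l, n = rep(1, l + 1),
                                  fragments = smoothAll,
                                  rate = smoothAll, smooth = smoothAll),
              smoothAll = smoothAll, sampleInfo = list())
    fr <- makeFragments("c1", c(100, 1200, 2500), c(199, 1299, 2599))
    bt <- addBinAnnotation(assignBins(fr, scheme), g, tr)
    bt <- singlePositionCorrect(bt, st, g, tr,
                                reciprocalMappability = FALSE)
    ## oracle: loop over every position on both strands
    s <- as.character(g[[1]])
    L <- nchar(s)
    gcOf <- function(x) sum(strsplit(x, "")[[1]] %in% c("G", "C"))
    agg <- numeric(3)
    for (pos in 1:(L - k + 1)) {
        if (!tr@flags$c1[pos]) next
        bPlus <- (pos - 1) %/% 1000 + 1
        if (pos + l - 1 <= L)
            agg[bPlus] <- agg[bPlus] +
                smoothAll[gcOf(substr(s, pos, pos + l - 1)) + 1]
        p5 <- pos + k - 1        # minus-strand 5' end for this k-mer
        bMinus <- (p5 - 1) %/% 1000 + 1
        if (p5 - l + 1 >= 1)
            agg[bMinus] <- agg[bMinus] +
                smoothAll[gcOf(substr(s, p5 - l + 1, p5)) + 1]
    }
    model <- binPositionModel(g, tr, scheme, l)
    got <- as.numeric(model$counts$all %*% smoothAll)
    expect_equal(got, agg, tolerance = 1e-9)
    expect_equal(correctedCounts(bt, "singlepos"),
                 rawCounts(bt) / agg, tolerance = 1e-9)
})

test_that("fully non-unique bins are invalidated by zero prediction", {
    g <- randomGenome(c(c1 = 3000), seed = 14)
    tr <- allUniqueTrack(g, 25)
    tr@flags$c1[976:2000] <- FALSE      # bin 2 has no unique starts
    l <- 30L
    st <- new("GCStrataTable", windowLength = l,
              strata = data.frame(gc = 0:l, n = rep(1, l + 1),
                                  fragments = rep(0.5, l + 1),
                                  rate = rep(0.5, l + 1),
                                  smooth = rep(0.5, l + 1)),
              smoothAll = rep(0.5, l + 1), sampleInfo = list())
    fr <- makeFragments("c1", c(100, 1200, 2500), c(199, 1299, 2599))
    bt <- addBinAnnotation(assignBins(fr, binScheme(g, 1000)), g, tr)
    bt <- singlePositionCorrect(bt, st, g, tr)
    expect_false(validBins(bt)[2])
    expect_true(is.na(correctedCounts(bt, "singlepos")[2]))
})

test_that("correction concentrates flat-truth bin values (variance drop)", {
    cfg <- simConfig(chromLengths = c(c1 = 6e5),
                     rateCurve = list(peak = 0.45, concentration = 30),
                     motifWeights = NULL, nFragments = 4e5,
                     gcWindow = 80L, fetalFraction = 0, seed = 21)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    st <- singlePositionFit(sim$fragments, g, tr, l = 80,
                            sampleSize = 4e5, seed = 22)
    bt <- addBinAnnotation(assignBins(sim$fragments, binScheme(g, 20000)),
                           g, tr)
    bt <- singlePositionCorrect(bt, st, g, tr)
    raw <- rawCounts(bt)
    corr <- correctedCounts(bt, "singlepos")
    cv <- function(x) sd(x) / mean(x)
    expect_lt(cv(corr), cv(raw))
})

test_that("corrected values simulated from the fitted model lose the GC slope", {
    ## block-heterogeneous genome so bins genuinely spread in GC
    cfg <- simConfig(chromLengths = c(c1 = 2e6), blockLength = 10000L,
                     motifWeights = NULL, fetalFraction = 0, seed = 25)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    scheme <- binScheme(g, 10000)
    l <- 60L
    smoothAll <- dbeta((0:l) / l, 1 + 0.45 * 30, 1 + 0.55 * 30) / 50
    st <- new("GCStrataTable", windowLength = l,
              strata = data.frame(gc = 0:l, n = rep(1, l + 1),
                                  fragments = smoothAll,
                                  rate = smoothAll, smooth = smoothAll),
              smoothAll = smoothAll, sampleInfo = list())
    model <- binPositionModel(g, tr, scheme, l)
    expected <- as.numeric(model$counts$all %*% smoothAll)
    set.seed(26)
    counts <- rpois(length(expected), expected * 50)  # ~2e4 per bin
    bt <- makeBinTable(counts, as.numeric(windowGC(g, scheme)),
                       binSize = 10000L, mappability = 1)
    bt <- singlePositionCorrect(bt, st, g, tr, model = model)
    corr <- correctedCounts(bt, "singlepos")
    y <- corr / mean(corr)
    slope <- coef(lm(y ~ binGC(bt)))[2]
    expect_lt(abs(slope), 0.02)
})

test_that("madError is the mean absolute difference", {
    expect_equal(madError(c(10, 20), c(12, 16)), 3)
    expect_equal(madError(5, 9), 4)
    expect_equal(madError(c(1, 2), c(1, 2)), 0)
    expect_error(madError(numeric(0), numeric(0)), "empty")
    expect_error(madError(1:3, 1:2), "align")
})

test_that("null fragments give near-zero TV across window lengths", {
    cfg <- simConfig(chromLengths = c(c1 = 4e5),
                     rateCurve = list(peak = 0.45, concentration = 0),
                     motifWeights = NULL, nFragments = 1e5,
                     gcWindow = 60L, fetalFraction = 0, seed = 33)
    g <- simulateGenome(cfg)
    tr <- allUniqueTrack(g, 50)
    sim <- simulateFragments(g, cfg)
    curve <- gcWindowScan(sim$fragments, g, tr,
                          windowLengths = c(5, 60, 180, 400),
                          nPositions = 5e4, seed = 34)
    ## the null noise floor grows with the number of occupied strata, so
    ## bound the observed scores by a permuted control at each length
    samp <- plasmaBias:::.samplePositions(g, tr, 5e4, 34)
    tab <- plasmaBias:::.p5Tab(sim$fragments, c(c1 = 4e5))
    F <- ifelse(samp$minus, tab$c1$minus[samp$pos],
                tab$c1$plus[samp$pos])
    cache <- plasmaBias:::.genomeCache(g)
    cc <- plasmaBias:::.cacheCodes(cache, "c1")
    set.seed(35)
    for (i in seq_along(curve@windowLengths)) {
        l <- curve@windowLengths[i]
        s <- plasmaBias:::.windowGCCounts(cc, samp$pos, l, FALSE)
        s[samp$minus] <- plasmaBias:::.windowGCCounts(
            cc, samp$pos[samp$minus], l, TRUE)
        ok <- !is.na(s)
        ctrl <- tvScore(tabulate(s[ok] + 1L, l + 1L),
                        plasmaBias:::.groupSum(sample(F[ok]),
                                               s[ok] + 1L, l + 1L))
        expect_lt(curve@scores[i], 2 * ctrl + 0.01)
        expect_lt(curve@scores[i], 0.1)
    }
})
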