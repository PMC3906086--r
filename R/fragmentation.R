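#' Base composition around fragment termini
#'
#' For each stringently mapped fragment (mapping quality at least
#' \code{mapqMin}), the reference context around the chosen terminus is
#' read out in fragment-strand orientation (minus-strand contexts are
#' reverse-complemented, so offset 0 is always a fragment base: the first
#' base for the 5' end, the last for the 3' end).  Per-offset base
#' proportions are returned; a fragment too close to a chromosome end
#' contributes only the offsets with valid context.
#'
#' @param frags \code{GRanges} of fragments with a \code{mapq} column
#'   (fragments without mapq pass the filter when \code{mapqMin} is NA).
#' @param genome \code{DNAStringSet}.
#' @param end \code{"5p"} or \code{"3p"}.
#' @param flank half-width of the window: offsets run from -flank to
#'   flank - 1 (default 25, giving -25..+24).
#' @param mapqMin minimum mapping quality (default 60).
#' @return a \code{\link{PositionalBaseProfile}}.
#' @export
baseProfile <- function(frags, genome, end = c("5p", "3p"), flank = 25L,
                        mapqMin = 60) {
    end <- match.arg(end)
    flank <- as.integer(flank)
    if (!is.na(mapqMin)) {
        mq <- mcols(frags)$mapq
        keep <- !is.na(mq) & mq >= mapqMin
        frags <- frags[keep]
    }
    if (length(frags) == 0L)
        stop("no fragments pass the mapq filter")
    .checkChromsKnown(seqnames(frags), names(genome))
    cache <- .genomeCache(genome)
    offsets <- seq.int(-flank, flank - 1L)
    counts <- matrix(0L, nrow = length(offsets), ncol = 4L,
                     dimnames = list(NULL, .BASES))
    used <- integer(length(offsets))
    fchrom <- as.character(seqnames(frags))
    str <- as.character(strand(frags))
    ## anchor: the terminal fragment base on the reference
    anchor <- if (end == "5p")
        ifelse(str == "+", start(frags), end(frags))
    else
        ifelse(str == "+", end(frags), start(frags))
    for (chrom in unique(fchrom)) {
        cc <- .cacheCodes(cache, chrom)
        L <- length(cc$codes)
        for (minus in c(FALSE, TRUE)) {
            sel <- fchrom == chrom & (str == "-") == minus
            if (!any(sel)) next
            a <- anchor[sel]
            for (i in seq_along(offsets)) {
                o <- offsets[i]
                p <- if (minus) a - o else a + o
                ok <- p >= 1L & p <= L
                b <- cc$codes[p[ok]]
                b <- b[!is.na(b)]
                if (minus) b <- 3L - b
                counts[i, ] <- counts[i, ] + tabulate(b + 1L, nbins = 4L)
                used[i] <- used[i] + length(b)
            }
        }
    }
    prop <- counts / pmax(rowSums(counts), 1L)
    new("PositionalBaseProfile", end = end, offsets = offsets,
        proportions = prop, counts = used)
}

## stratify sampled positions by the bases at a set of offsets
## (read-strand orientation); returns per-position stratum index or NA
.offsetStrata <- function(cache, samp, offsets) {
    nOff <- length(offsets)
    strat <- rep(0L, nrow(samp))
    bad <- rep(FALSE, nrow(samp))
    for (chrom in unique(samp$chrom)) {
        cc <- .cacheCodes(cache, chrom)
        L <- length(cc$codes)
        for (minus in c(FALSE, TRUE)) {
            sel <- which(samp$chrom == chrom & samp$minus == minus)
            if (!length(sel)) next
            pos <- samp$pos[sel]
            acc <- rep(0L, length(sel))
            badLocal <- rep(FALSE, length(sel))
            for (o in offsets) {
                p <- if (minus) pos - o else pos + o
                ok <- p >= 1L & p <= L
                b <- rep(NA_integer_, length(sel))
                b[ok] <- cc$codes[p[ok]]
                if (minus) b <- 3L - b
                badLocal <- badLocal | is.na(b)
                b[is.na(b)] <- 0L
                acc <- acc * 4L + b
            }
            strat[sel] <- acc
            bad[sel] <- badLocal
        }
    }
    strat[bad] <- NA_integer_
    strat + 1L  # 1 .. 4^nOff
}

#' TV score conditioned on breakpoint-flanking bases
#'
#' Sampled uniquely mappable positions are stratified by the k-mer over
#' the conditioned offsets plus one candidate offset (relative to the 5'
#' fragment start, read-strand orientation), and the TV score of the
#' resulting strata is returned.  Comparing candidates reveals which
#' positions around the cleavage site carry fragmentation bias.
#'
#' @param frags,genome,track as in \code{\link{gcWindowScan}}.
#' @param conditioned integer offsets already conditioned on (may be
#'   empty).
#' @param candidate one additional offset to assess.
#' @param nPositions,seed position sample size and seed.
#' @return the TV score.
#' @export
positionalTV <- function(frags, genome, track, conditioned = integer(),
                         candidate, nPositions = 5e4, seed = 1L) {
    cache <- .genomeCache(genome)
    lens <- .seqLengths(genome)
    samp <- .samplePositions(genome, track, nPositions, seed)
    tab <- .p5Tab(frags, lens)
    F <- integer(nrow(samp))
    for (chrom in unique(samp$chrom)) {
        for (minus in c(FALSE, TRUE)) {
            sel <- samp$chrom == chrom & samp$minus == minus
            if (!any(sel)) next
            v <- if (minus) tab[[chrom]]$minus else tab[[chrom]]$plus
            F[sel] <- v[samp$pos[sel]]
        }
    }
    offsets <- sort(unique(c(conditioned, candidate)))
    strat <- .offsetStrata(cache, samp, offsets)
    ok <- !is.na(strat)
    if (sum(ok) < 1000L)
        stop("fewer than 1000 usable positions")
    ngroups <- 4L^length(offsets)
    ns <- tabulate(strat[ok], nbins = ngroups)
    fs <- .groupSum(F[ok], strat[ok], ngroups)
    tvScore(ns, fs)
}

#' Greedy selection of influential breakpoint offsets
#'
#' Starting from the empty set, repeatedly adds the offset whose
#' inclusion gives the largest TV score, until the gain drops below
#' \code{gainTol} or \code{maxK} offsets are selected.  One position
#' sample is shared across all evaluations.
#'
#' @param frags,genome,track as in \code{\link{gcWindowScan}}.
#' @param candidates offsets considered (default -25..24).
#' @param maxK maximum number of offsets (at most 6; stratification by
#'   more than a 6-mer is never informative at desk scale).
#' @param gainTol minimum TV gain to continue (default 0.005).
#' @param nPositions,seed position sample size and seed.
#' @return list with \code{offsets} (selection order), \code{scores}
#'   (TV after each addition) and \code{gains}.
#' @export
greedyMotifPositions <- function(frags, genome, track,
                                 candidates = -25:24, maxK = 3L,
                                 gainTol = 0.005, nPositions = 5e4,
                                 seed = 1L) {
    if (maxK > 6L)
        stop("maxK must be at most 6")
    cache <- .genomeCache(genome)
    lens <- .seqLengths(genome)
    samp <- .samplePositions(genome, track, nPositions, seed)
    tab <- .p5Tab(frags, lens)
    F <- integer(nrow(samp))
    for (chrom in unique(samp$chrom)) {
        for (minus in c(FALSE, TRUE)) {
            sel <- samp$chrom == chrom & samp$minus == minus
            if (!any(sel)) next
            v <- if (minus) tab[[chrom]]$minus else tab[[chrom]]$plus
            F[sel] <- v[samp$pos[sel]]
        }
    }
    score1 <- function(offsets) {
        strat <- .offsetStrata(cache, samp, offsets)
        ok <- !is.na(strat)
        ngroups <- 4L^length(offsets)
        ns <- tabulate(strat[ok], nbins = ngroups)
        fs <- .groupSum(F[ok], strat[ok], ngroups)
        tvScore(ns, fs)
    }
    chosen <- integer()
    scores <- numeric()
    gains <- numeric()
    prev <- 0
    while (length(chosen) < maxK) {
        rest <- setdiff(candidates, chosen)
        if (!length(rest)) break
        tv <- vapply(rest, function(o) score1(c(chosen, o)), numeric(1))
        best <- which.max(tv)
        gain <- tv[best] - prev
        if (gain < gainTol) break
        chosen <- c(chosen, rest[best])
        scores <- c(scores, tv[best])
        gains <- c(gains, gain)
        prev <- tv[best]
    }
    list(offsets = chosen, scores = scores, gains = gains)
}

#' Breakpoint 3-mer frequency table
#'
#' Counts the 64 breakpoint 3-mers (reference bases at offsets -2, 0, +1
#' around the 5' fragment start, read-strand orientation) separately for
#' plus- and minus-strand fragments.  Fragments whose context contains N
#' or leaves the chromosome are excluded and counted.
#'
#' @param frags \code{GRanges} with \code{mapq} column.
#' @param genome \code{DNAStringSet}.
#' @param mapqMin minimum mapping quality (default 60; NA disables the
#'   filter).
#' @return a \code{\link{MotifFrequencyTable}}.
#' @export
motifTable <- function(frags, genome, mapqMin = 60) {
    if (!is.na(mapqMin)) {
        mq <- mcols(frags)$mapq
        frags <- frags[!is.na(mq) & mq >= mapqMin]
    }
    .checkChromsKnown(seqnames(frags), names(genome))
    cache <- .genomeCache(genome)
    counts <- matrix(0L, nrow = 64L, ncol = 2L,
                     dimnames = list(breakpointMotifs(),
                                     c("plus", "minus")))
    excluded <- c(plus = 0L, minus = 0L)
    fchrom <- as.character(seqnames(frags))
    str <- as.character(strand(frags))
    p5 <- .fivePrimeEnds(frags)
    for (chrom in unique(fchrom)) {
        cc <- .cacheCodes(cache, chrom)
        for (minus in c(FALSE, TRUE)) {
            sel <- fchrom == chrom & (str == "-") == minus
            if (!any(sel)) next
            idx <- .motifIndex(cc$codes, p5[sel], minus)
            col <- if (minus) 2L else 1L
            counts[, col] <- counts[, col] +
                tabulate(idx[!is.na(idx)], nbins = 64L)
            excluded[col] <- excluded[col] + sum(is.na(idx))
        }
    }
    new("MotifFrequencyTable", counts = counts, excluded = excluded)
}

#' Motif proportions and the top-20-plus-rest partition
#'
#' @param table a \code{\link{MotifFrequencyTable}}.
#' @param nTop number of motifs kept individually (default 20); the
#'   remaining motifs are aggregated into one "rest" class.  Motifs are
#'   ranked by their pooled count over both strands so the same
#'   categories apply to each strand.
#' @return a \code{(nTop + 1) x 2} count matrix.
#' @export
motifTopTable <- function(table, nTop = 20L) {
    total <- rowSums(table@counts)
    ord <- order(total, decreasing = TRUE)
    top <- ord[seq_len(nTop)]
    rest <- colSums(table@counts[-top, , drop = FALSE])
    out <- rbind(table@counts[top, , drop = FALSE], rest = rest)
    out
}

#' Chi-square test for strand homogeneity of motif usage
#'
#' Tests whether plus- and minus-strand fragments draw their breakpoint
#' 3-mers from the same multinomial distribution, on the common top-20
#' motifs plus the aggregated rest class (21 categories, df = 20).
#'
#' @param table a \code{\link{MotifFrequencyTable}}.
#' @param nTop number of motif categories kept individually.
#' @return list with \code{statistic}, \code{df}, \code{p.value} and the
#'   contingency \code{table} used.
#' @export
strandHomogeneityTest <- function(table, nTop = 20L) {
    tab <- motifTopTable(table, nTop)
    if (any(colSums(tab) == 0))
        stop("both strands must have fragments")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5))
        warning("expected cell count below 5; chi-square approximation ",
                "may be poor")
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p.value = unname(res$p.value), table = tab)
}

#' Assign fragments to breakpoint-motif strata
#'
#' Stratum 1 holds fragments whose 5' breakpoint 3-mer (read from the
#' reference at the mapped position) belongs to \code{motifs}; all other
#' fragments form stratum 2.  Fragments with undefined context (N or
#' chromosome edge) get NA and are excluded from the stratum weights.
#'
#' @param frags \code{GRanges} of fragments.
#' @param genome \code{DNAStringSet}.
#' @param motifs stratum-1 motif set; the default is the four GC-shifted
#'   high-frequency motifs C*CC, C*GG, C*CA, C*TG.
#' @return a \code{\link{StratumAssignment}}.
#' @export
assignStrata <- function(frags, genome,
                         motifs = c("C*CC", "C*GG", "C*CA", "C*TG")) {
    .checkChromsKnown(seqnames(frags), names(genome))
    cache <- .genomeCache(genome)
    all64 <- breakpointMotifs()
    if (!all(motifs %in% all64))
        stop("unknown motif(s): ",
             paste(setdiff(motifs, all64), collapse = ", "))
    motifSet <- match(motifs, all64)
    fchrom <- as.character(seqnames(frags))
    str <- as.character(strand(frags))
    p5 <- .fivePrimeEnds(frags)
    stratum <- rep(NA_integer_, length(frags))
    if (length(unique(motifs)) == 64L) {
        ## every possible context is in the set: membership is vacuous
        stratum[] <- 1L
    } else for (chrom in unique(fchrom)) {
        cc <- .cacheCodes(cache, chrom)
        for (minus in c(FALSE, TRUE)) {
            sel <- which(fchrom == chrom & (str == "-") == minus)
            if (!length(sel)) next
            idx <- .motifIndex(cc$codes, p5[sel], minus)
            stratum[sel] <- ifelse(is.na(idx), NA_integer_,
                                   ifelse(idx %in% motifSet, 1L, 2L))
        }
    }
    nOk <- sum(!is.na(stratum))
    if (nOk == 0L)
        stop("no fragment has a defined breakpoint context")
    w1 <- sum(stratum == 1L, na.rm = TRUE) / nOk
    new("StratumAssignment", motifs = motifs, stratum = stratum,
        weights = c(w1, 1 - w1))
}

#' Motif-stratified single-position GC correction
#'
#' The single-position model is fitted and evaluated separately within
#' the two breakpoint-motif strata (positions are partitioned by their
#' own reference-determined motif, so fragments starting at a stratum-k
#' position are exactly the stratum-k fragments).  Per bin, each
#' stratum's observed count is normalized by its stratum prediction and
#' the two corrected values are combined with the sample-wide stratum
#' proportions as weights (or per-bin read proportions when
#' \code{perBinWeights = TRUE}); finally the reciprocal-mappability
#' factor is applied as in \code{\link{singlePositionCorrect}}.
#'
#' @param bins annotated \code{\link{BinTable}}.
#' @param frags \code{GRanges} of fragments.
#' @param genome,track as elsewhere.
#' @param assignment a \code{\link{StratumAssignment}}.
#' @param l GC window length (bp).
#' @param sampleSize,seed position sample for the stratum fits.
#' @param reciprocalMappability,predTol,mappabilityCutoff as in
#'   \code{\link{singlePositionCorrect}}.
#' @param model optional precomputed \code{\link{binPositionModel}} built
#'   with the same \code{motifs}.
#' @param perBinWeights combine strata with per-bin read proportions
#'   instead of sample-wide weights.
#' @param method name for the stored correction.
#' @return the \code{BinTable} with a \code{corrected.<method>} column.
#' @export
stratifiedCorrect <- function(bins, frags, genome, track, assignment,
                              l, sampleSize = 5e6, seed = 1L,
                              reciprocalMappability = TRUE,
                              predTol = 1e-8, model = NULL,
                              perBinWeights = FALSE,
                              method = "singlepos_frag",
                              mappabilityCutoff = 0.5) {
    l <- as.integer(l)
    mc <- mcols(bins@bins)
    if (!"mappability" %in% colnames(mc))
        stop("mappability not populated; run addBinAnnotation() first")
    if (is.null(model))
        model <- binPositionModel(genome, track, bins@bins, l,
                                  motifs = assignment@motifs)
    if (is.null(model$counts$s1))
        stop("model was not built with motif strata")
    cache <- .genomeCache(genome)
    lens <- .seqLengths(genome)
    motifSet <- match(assignment@motifs, breakpointMotifs())
    coversAll <- length(unique(assignment@motifs)) == 64L

    ## sample positions once; split by their motif stratum
    samp <- .samplePositions(genome, track, sampleSize, seed)
    s <- rep(NA_integer_, nrow(samp))
    pm <- rep(NA_integer_, nrow(samp))
    for (chrom in unique(samp$chrom)) {
        cc <- .cacheCodes(cache, chrom)
        for (minus in c(FALSE, TRUE)) {
            sel <- which(samp$chrom == chrom & samp$minus == minus)
            if (!length(sel)) next
            s[sel] <- .windowGCCounts(cc, samp$pos[sel], l, minus)
            pm[sel] <- .motifIndex(cc$codes, samp$pos[sel], minus)
        }
    }
    ok <- if (coversAll) !is.na(s) else !is.na(s) & !is.na(pm)
    samp <- samp[ok, , drop = FALSE]
    s <- s[ok]
    posStr <- if (coversAll) rep(1L, nrow(samp))
              else ifelse(pm[ok] %in% motifSet, 1L, 2L)

    tab <- .p5Tab(frags, lens)
    F <- integer(nrow(samp))
    for (chrom in unique(samp$chrom)) {
        for (minus in c(FALSE, TRUE)) {
            sel <- samp$chrom == chrom & samp$minus == minus
            if (!any(sel)) next
            v <- if (minus) tab[[chrom]]$minus else tab[[chrom]]$plus
            F[sel] <- v[samp$pos[sel]]
        }
    }

    fitStratum <- function(k) {
        keep <- posStr == k
        ns <- tabulate(s[keep] + 1L, nbins = l + 1L)
        fs <- .groupSum(F[keep], s[keep] + 1L, l + 1L)
        occ <- which(ns > 0L)
        if (length(occ) < 10L)
            stop("motif stratum ", k, " has fewer than 10 occupied GC ",
                 "strata; use a larger input")
        rate <- fs[occ] / ns[occ]
        gcv <- occ - 1L
        lo <- stats::loess(rate ~ gcv, weights = ns[occ],
                           span = max(0.3, min(1, 8 / length(occ))),
                           degree = 2,
                           control = stats::loess.control(
                               surface = "direct"))
        smoothOcc <- pmax(as.numeric(stats::fitted(lo)), 0)
        smoothAll <- pmax(stats::approx(gcv, smoothOcc, xout = 0:l,
                                        rule = 2)$y, 0)
        st <- data.frame(gc = gcv, n = ns[occ], fragments = fs[occ],
                         rate = rate, smooth = smoothOcc)
        new("GCStrataTable", windowLength = l, strata = st,
            smoothAll = smoothAll,
            sampleInfo = list(nPositions = sum(keep), seed = seed))
    }
    fit1 <- fitStratum(1L)
    fit2 <- if (coversAll) NULL else fitStratum(2L)

    ## per-bin observed counts per fragment stratum
    obs <- matrix(0, nrow = model$nbin, ncol = 2L)
    chroms <- as.character(seqnames(bins@bins))
    fchrom <- as.character(seqnames(frags))
    p5 <- .fivePrimeEnds(frags)
    for (chrom in unique(fchrom)) {
        binIdx0 <- which(chroms == chrom)
        nb <- length(binIdx0)
        sel <- which(fchrom == chrom)
        b <- (p5[sel] - 1L) %/% model$binSize + 1L
        for (k in 1:2) {
            inK <- !is.na(assignment@stratum[sel]) &
                assignment@stratum[sel] == k & b >= 1L & b <= nb
            obs[binIdx0, k] <- obs[binIdx0, k] +
                tabulate(b[inK], nbins = nb)
        }
    }
    pred1 <- as.numeric(model$counts$s1 %*% fit1@smoothAll)
    m <- mc$mappability
    if (coversAll) {
        valid <- validBins(bins) & m >= mappabilityCutoff &
            pred1 > predTol
        combined <- obs[, 1] / pred1
    } else {
        pred2 <- as.numeric(model$counts$s2 %*% fit2@smoothAll)
        valid <- validBins(bins) & m >= mappabilityCutoff &
            pred1 > predTol & pred2 > predTol
        c1 <- obs[, 1] / pred1
        c2 <- obs[, 2] / pred2
        if (perBinWeights) {
            tot <- obs[, 1] + obs[, 2]
            w1 <- ifelse(tot > 0, obs[, 1] / tot, assignment@weights[1])
            combined <- w1 * c1 + (1 - w1) * c2
        } else {
            combined <- assignment@weights[1] * c1 +
                assignment@weights[2] * c2
        }
    }
    corrected <- rep(NA_real_, model$nbin)
    corrected[valid] <- combined[valid]
    if (reciprocalMappability)
        corrected[valid] <- corrected[valid] / m[valid]
    mcols(bins@bins)$valid <- valid
    mcols(bins@bins)[[paste0("corrected.", method)]] <- corrected
    validObject(bins)
    attr(bins, "stratumFits") <- list(fit1, fit2)
    bins
}
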