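#' Binned LOESS GC correction
#'
#' Implements the classic windowed GC correction: valid bins are grouped
#' by GC content into 1\% intervals, the mean count of the non-zero bins
#' in each occupied interval is computed, and a LOESS curve (span 0.3 by
#' default) is fitted to the (interval midpoint, mean count) pairs.  Each
#' bin's predicted count is the fit evaluated at the bin's GC (linear
#' interpolation between fitted midpoints, held constant at the edges)
#' and its corrected value is count / prediction.  Bins with zero count
#' are excluded from the fit but still receive a prediction and a
#' corrected value of 0.
#'
#' @param bins a \code{\link{BinTable}} with \code{gc} populated.
#' @param span LOESS span (default 0.3).
#' @param countColumn which counts to correct: \code{"raw"} or a stored
#'   correction name such as \code{"mapcorr"}.
#' @param method name under which the corrected values are stored
#'   (column \code{corrected.<method>}).
#' @param fitToBins fit the LOESS to all non-zero bins directly instead
#'   of to the 1\% interval means.
#' @return list with elements \code{bins} (the updated \code{BinTable})
#'   and \code{fit} (a \code{\link{LoessFit}}).
#' @export
loessGCCorrect <- function(bins, span = 0.3, countColumn = "raw",
                           method = "loess", fitToBins = FALSE) {
    mc <- mcols(bins@bins)
    if (!"gc" %in% colnames(mc))
        stop("gc not populated; run addBinAnnotation() first")
    counts <- if (countColumn == "raw") as.numeric(mc$raw_count)
              else correctedCounts(bins, countColumn)
    use <- validBins(bins) & analysisBins(bins) & !is.na(counts) &
        is.finite(mc$gc)
    gcPct <- mc$gc * 100
    interval <- pmin(floor(gcPct), 99)
    fitIdx <- use & counts > 0
    occ <- sort(unique(interval[fitIdx]))
    if (length(occ) < 5L)
        stop("fewer than 5 occupied GC intervals (", length(occ),
             "); cannot fit LOESS")
    if (fitToBins) {
        fitX <- gcPct[fitIdx]
        fitY <- counts[fitIdx]
    } else {
        fitX <- occ + 0.5
        fitY <- vapply(occ, function(i)
            mean(counts[fitIdx & interval == i]), numeric(1))
    }
    lo <- stats::loess(y ~ x, data = data.frame(x = fitX, y = fitY),
                       span = max(span, min(1, 8 / length(fitX))),
                       degree = 2,
                       control = stats::loess.control(surface = "direct"))
    mids <- occ + 0.5
    fitted <- as.numeric(stats::predict(lo, newdata = data.frame(x = mids)))
    pred <- rep(NA_real_, length(counts))
    pred[use] <- stats::approx(mids, fitted, xout = gcPct[use],
                               rule = 2)$y
    if (any(pred[use] <= 0))
        stop("nonpositive LOESS prediction at ", sum(pred[use] <= 0),
             " bin(s); GC model unusable for this input")
    corrected <- rep(NA_real_, length(counts))
    corrected[use] <- counts[use] / pred[use]
    mcols(bins@bins)[[paste0("corrected.", method)]] <- corrected
    fit <- new("LoessFit", span = span,
               table = data.frame(mid = mids,
                                  meanCount = if (fitToBins)
                                      vapply(occ, function(i)
                                          mean(counts[fitIdx &
                                                      interval == i]),
                                          numeric(1)) else fitY,
                                  fitted = fitted),
               predictions = pred)
    list(bins = bins, fit = fit)
}

#' Total variation from independence (TV) score
#'
#' Measures how much of the variation in fragment coverage is explained
#' by a stratification of positions: the half-L1 distance between the
#' distribution of fragments over strata and the distribution of
#' positions over strata,
#' \deqn{TV = \frac12 \sum_s | F_s/\sum F - n_s/\sum n |.}
#' The score is 0 iff the fragment rate is constant across strata and at
#' most 1; strata with no positions and no fragments contribute 0.
#'
#' @param n positions per stratum.
#' @param fragments fragments per stratum.
#' @return TV score in [0, 1].
#' @examples
#' tvScore(c(10, 30, 60), c(5, 10, 5))  # 0.35
#' @export
tvScore <- function(n, fragments) {
    if (length(n) != length(fragments))
        stop("n and fragments must align")
    if (any(n < 0) || any(fragments < 0))
        stop("stratum counts must be non-negative")
    sn <- sum(n)
    sf <- sum(fragments)
    if (sn <= 0)
        stop("no positions in any stratum")
    if (sf <= 0)
        stop("no fragments in any stratum")
    0.5 * sum(abs(fragments / sf - n / sn))
}

## eligible 5'-end positions on a strand: uniquely mappable (the aligned
## k-mer is [x, x+k-1] for +, [x-k+1, x] for -) and inside the chromosome
.eligible5p <- function(track, chrom, minus) {
    f <- track@flags[[chrom]]
    pos <- which(f)
    if (minus) pos + track@k - 1L else pos
}

## per-chromosome, per-strand tabulation of fragment 5' ends
.p5Tab <- function(frags, lens) {
    fchrom <- as.character(seqnames(frags))
    str <- as.character(strand(frags))
    p5 <- .fivePrimeEnds(frags)
    out <- list()
    for (chrom in names(lens)) {
        sel <- fchrom == chrom
        out[[chrom]] <- list(
            plus = tabulate(p5[sel & str == "+"], nbins = lens[[chrom]]),
            minus = tabulate(p5[sel & str == "-"], nbins = lens[[chrom]]))
    }
    out
}

## draw a strand-specific sample of uniquely mappable 5'-end positions.
## Returns data.frame(chrom, pos, minus) of size <= nPositions.
.samplePositions <- function(genome, track, nPositions, seed) {
    chroms <- names(track@flags)
    pools <- list()
    for (chrom in chroms) {
        for (minus in c(FALSE, TRUE)) {
            pos <- .eligible5p(track, chrom, minus)
            if (length(pos))
                pools[[length(pools) + 1L]] <-
                    list(chrom = chrom, minus = minus, pos = pos)
        }
    }
    sizes <- vapply(pools, function(p) length(p$pos), numeric(1))
    total <- sum(sizes)
    if (total == 0L)
        stop("no uniquely mappable positions available")
    take <- min(nPositions, total)
    idx <- .withSeed(seed, sort(sample(total, take)))
    offsets <- c(0, cumsum(sizes))
    out <- vector("list", length(pools))
    for (i in seq_along(pools)) {
        local <- idx[idx > offsets[i] & idx <= offsets[i + 1L]] - offsets[i]
        if (length(local))
            out[[i]] <- data.frame(chrom = pools[[i]]$chrom,
                                   pos = pools[[i]]$pos[local],
                                   minus = pools[[i]]$minus)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Scan TV scores across GC window lengths
#'
#' A single strand-specific sample of uniquely mappable positions is
#' drawn and shared across all window lengths.  For each length l, every
#' sampled position is assigned the GC count of the length-l window
#' anchored at the position in read-strand orientation (for minus-strand
#' positions the window ends at the position), positions whose window
#' leaves the chromosome or contains N are excluded for that l, and the
#' TV score of the resulting strata is computed.
#'
#' @param frags \code{GRanges} of fragments.
#' @param genome \code{DNAStringSet}.
#' @param track \code{\link{MappabilityTrack}}.
#' @param windowLengths lengths to scan (default 1:700 bp; plasma
#'   fragments are essentially all shorter than 500 bp).
#' @param nPositions number of positions to sample (default 1e5).
#' @param seed integer seed for the position sample.
#' @return a \code{\link{TVScoreCurve}}.
#' @export
gcWindowScan <- function(frags, genome, track, windowLengths = 1:700,
                         nPositions = 1e5, seed = 1L) {
    windowLengths <- as.integer(windowLengths)
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
    groups <- split(seq_len(nrow(samp)),
                    paste0(samp$chrom, ifelse(samp$minus, "-", "+")))
    scores <- vapply(windowLengths, function(l) {
        s <- rep(NA_integer_, nrow(samp))
        for (g in groups) {
            chrom <- samp$chrom[g[1]]
            minus <- samp$minus[g[1]]
            cc <- .cacheCodes(cache, chrom)
            s[g] <- .windowGCCounts(cc, samp$pos[g], l, minus)
        }
        ok <- !is.na(s)
        if (sum(ok) < 1000L)
            stop("fewer than 1000 usable positions at window length ", l)
        ns <- tabulate(s[ok] + 1L, nbins = l + 1L)
        fs <- .groupSum(F[ok], s[ok] + 1L, l + 1L)
        if (sum(fs) == 0)
            return(NA_real_)
        tvScore(ns, fs)
    }, numeric(1))
    new("TVScoreCurve", windowLengths = windowLengths,
        scores = scores, selected = NA_integer_)
}

#' Select the GC window length from a TV-score curve
#'
#' The sub-10 bp spike in plasma data reflects breakpoint motifs, not
#' fragment-scale GC dependence, so selection is restricted to window
#' lengths in \code{eligible} (default [50, 500] bp).  If the restricted
#' curve is flat (max - median below \code{flatTol}) no maximum is
#' trusted and the nucleosome-scale fallback of 180 bp is returned.
#'
#' @param curve a \code{\link{TVScoreCurve}}.
#' @param eligible length range considered, in bp.
#' @param flatTol flatness tolerance (default 0.005).
#' @param fallback window returned for a flat curve (default 180 bp,
#'   about the length of DNA in a nucleosome plus linker).
#' @return the curve with its \code{selected} slot filled in.
#' @export
selectGCWindow <- function(curve, eligible = c(50L, 500L),
                           flatTol = 0.005, fallback = 180L) {
    keep <- curve@windowLengths >= eligible[1] &
        curve@windowLengths <= eligible[2] & !is.na(curve@scores)
    if (!any(keep)) {
        curve@selected <- as.integer(fallback)
        return(curve)
    }
    sc <- curve@scores[keep]
    wl <- curve@windowLengths[keep]
    if (max(sc) - stats::median(sc) < flatTol)
        curve@selected <- as.integer(fallback)
    else
        curve@selected <- wl[which.max(sc)]
    curve
}

#' Fit the single-position GC bias model
#'
#' Uniquely mappable 5'-end positions are sampled on both strands and
#' stratified by the integer GC count of the length-l window anchored at
#' the position (strand-oriented).  For each stratum the mean fragment
#' rate is the ratio of fragments starting at the sampled positions to
#' the number of sampled positions, and the rate curve over strata is
#' smoothed by local regression weighted by stratum occupancy, clamped at
#' zero.
#'
#' @param frags \code{GRanges} of fragments.
#' @param genome \code{DNAStringSet}.
#' @param track \code{\link{MappabilityTrack}}.
#' @param l GC window length in bp (see \code{\link{selectGCWindow}}).
#' @param sampleSize number of positions to sample (default
#'   \code{5e6}; all positions are used when fewer are available).
#' @param seed integer seed.
#' @param span smoothing span for the rate curve (default 0.3).
#' @return a \code{\link{GCStrataTable}}.
#' @export
singlePositionFit <- function(frags, genome, track, l, sampleSize = 5e6,
                              seed = 1L, span = 0.3) {
    l <- as.integer(l)
    if (l < 1L)
        stop("window length l must be >= 1")
    cache <- .genomeCache(genome)
    lens <- .seqLengths(genome)
    samp <- .samplePositions(genome, track, sampleSize, seed)
    s <- rep(NA_integer_, nrow(samp))
    for (chrom in unique(samp$chrom)) {
        cc <- .cacheCodes(cache, chrom)
        for (minus in c(FALSE, TRUE)) {
            sel <- samp$chrom == chrom & samp$minus == minus
            if (any(sel))
                s[sel] <- .windowGCCounts(cc, samp$pos[sel], l, minus)
        }
    }
    ok <- !is.na(s)          # windows leaving the chromosome or with N
    samp <- samp[ok, , drop = FALSE]
    s <- s[ok]
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
    ns <- tabulate(s + 1L, nbins = l + 1L)
    fs <- .groupSum(F, s + 1L, l + 1L)
    occ <- which(ns > 0L)
    if (length(occ) < 10L)
        stop("fewer than 10 occupied GC strata (", length(occ),
             "); use a larger sample or smaller window")
    rate <- fs[occ] / ns[occ]
    gcv <- occ - 1L
    lo <- stats::loess(rate ~ gcv, weights = ns[occ],
                       span = max(span, min(1, 8 / length(occ))),
                       degree = 2,
                       control = stats::loess.control(surface = "direct"))
    smoothOcc <- pmax(as.numeric(stats::fitted(lo)), 0)
    smoothAll <- pmax(stats::approx(gcv, smoothOcc, xout = 0:l,
                                    rule = 2)$y, 0)
    st <- data.frame(gc = gcv, n = ns[occ], fragments = fs[occ],
                     rate = rate, smooth = smoothOcc)
    new("GCStrataTable", windowLength = l, strata = st,
        smoothAll = smoothAll,
        sampleInfo = list(nPositions = nrow(samp), seed = seed))
}

#' Precompute per-bin stratum occupancy for the single-position model
#'
#' For every uniquely mappable position on both strands whose GC window is
#' defined, tallies how many fall in each (bin, GC stratum) cell, and
#' optionally splits the tally by breakpoint-motif stratum.  The
#' aggregated per-bin prediction for any fitted rate curve is then a
#' single matrix product, so the expensive genome pass is done once per
#' (genome, scheme, l) and reused across samples.
#'
#' @param genome \code{DNAStringSet}.
#' @param track \code{\link{MappabilityTrack}}.
#' @param scheme bin scheme (\code{GRanges} from \code{\link{binScheme}}).
#' @param l GC window length in bp.
#' @param motifs optional stratum-1 breakpoint 3-mer set; when given the
#'   tallies are returned separately for motif stratum 1 and 2.
#' @return an object of class \code{binPositionModel} with matrices of
#'   bins x (l + 1) stratum occupancies.
#' @export
binPositionModel <- function(genome, track, scheme, l, motifs = NULL) {
    l <- as.integer(l)
    cache <- .genomeCache(genome)
    chroms <- as.character(seqnames(scheme))
    binSize <- unique(width(scheme))[1]
    nbin <- length(scheme)
    nstr <- l + 1L
    motifSet <- if (!is.null(motifs)) match(motifs, breakpointMotifs())
    tallies <- if (is.null(motifs)) list(all = numeric(nbin * nstr))
               else list(s1 = numeric(nbin * nstr),
                         s2 = numeric(nbin * nstr))
    for (chrom in unique(chroms)) {
        cc <- .cacheCodes(cache, chrom)
        binIdx0 <- which(chroms == chrom)  # global bin indices, in order
        nb <- length(binIdx0)
        for (minus in c(FALSE, TRUE)) {
            pos <- .eligible5p(track, chrom, minus)
            if (!length(pos)) next
            s <- .windowGCCounts(cc, pos, l, minus)
            b <- (pos - 1L) %/% binSize + 1L
            ok <- !is.na(s) & b <= nb
            pos <- pos[ok]; s <- s[ok]; b <- b[ok]
            cell <- (binIdx0[b] - 1L) * nstr + s + 1L
            if (is.null(motifs)) {
                tallies$all <- tallies$all +
                    tabulate(cell, nbins = nbin * nstr)
            } else if (length(unique(motifs)) == 64L) {
                ## full motif set: stratum 1 holds every position
                tallies$s1 <- tallies$s1 +
                    tabulate(cell, nbins = nbin * nstr)
            } else {
                m <- .motifIndex(cc$codes, pos, minus)
                in1 <- !is.na(m) & m %in% motifSet
                tallies$s1 <- tallies$s1 +
                    tabulate(cell[in1], nbins = nbin * nstr)
                tallies$s2 <- tallies$s2 +
                    tabulate(cell[!in1], nbins = nbin * nstr)
            }
        }
    }
    out <- list(l = l, nbin = nbin, binSize = binSize,
                motifs = motifs,
                counts = lapply(tallies, function(x)
                    matrix(x, nrow = nbin, ncol = nstr, byrow = TRUE)))
    class(out) <- "binPositionModel"
    out
}

#' Single-position GC correction of bin counts
#'
#' Every uniquely mappable position receives the smoothed rate of its GC
#' stratum as its predicted fragment rate (0 at non-unique positions),
#' predictions are aggregated over each bin on both strands, and the
#' bin's corrected value is raw count / aggregated prediction, multiplied
#' by the reciprocal of the bin's mappability (set
#' \code{reciprocalMappability = FALSE} to skip that second factor).
#' Bins with aggregated prediction below \code{predTol} or mappability
#' below 0.5 are invalidated.
#'
#' @param bins annotated \code{\link{BinTable}} (needs mappability).
#' @param strata fitted \code{\link{GCStrataTable}}.
#' @param genome \code{DNAStringSet}.
#' @param track \code{\link{MappabilityTrack}}.
#' @param reciprocalMappability apply the 1/mappability factor on top of
#'   the zeroed predictions at non-unique positions (default TRUE).
#' @param predTol minimum aggregated prediction for a bin to stay valid.
#' @param model optional precomputed \code{\link{binPositionModel}}.
#' @param method name for the stored correction (default "singlepos").
#' @param mappabilityCutoff bins below this mappability are invalidated.
#' @return the \code{BinTable} with a \code{corrected.<method>} column.
#' @export
singlePositionCorrect <- function(bins, strata, genome, track,
                                  reciprocalMappability = TRUE,
                                  predTol = 1e-8, model = NULL,
                                  method = "singlepos",
                                  mappabilityCutoff = 0.5) {
    mc <- mcols(bins@bins)
    if (!"mappability" %in% colnames(mc))
        stop("mappability not populated; run addBinAnnotation() first")
    if (is.null(model))
        model <- binPositionModel(genome, track, bins@bins,
                                  strata@windowLength)
    if (model$l != strata@windowLength)
        stop("model window length does not match strata")
    occup <- if (!is.null(model$counts$all)) model$counts$all
             else model$counts$s1 + model$counts$s2
    agg <- as.numeric(occup %*% strata@smoothAll)
    m <- mc$mappability
    valid <- validBins(bins) & m >= mappabilityCutoff & agg > predTol
    corrected <- rep(NA_real_, length(agg))
    corrected[valid] <- mc$raw_count[valid] / agg[valid]
    if (reciprocalMappability)
        corrected[valid] <- corrected[valid] / m[valid]
    mcols(bins@bins)$valid <- valid
    mcols(bins@bins)[[paste0("corrected.", method)]] <- corrected
    validObject(bins)
    bins
}

#' Mean absolute deviation between observed and predicted counts
#'
#' The prediction error used to compare repeat-handling protocols: the
#' mean of |observed - predicted| over bins.
#'
#' @param observed,predicted equal-length numeric vectors over valid
#'   bins.
#' @return the mean absolute deviation.
#' @examples
#' madError(c(10, 20), c(12, 16))  # 3
#' @export
madError <- function(observed, predicted) {
    if (length(observed) != length(predicted))
        stop("observed and predicted must align")
    if (length(observed) == 0L)
        stop("empty input")
    mean(abs(observed - predicted))
}
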