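#' Configuration for the plasma-DNA simulator
#'
#' Defines a toy genome and a plasma-like fragment generator with known
#' ground truth: block-wise GC heterogeneity, optional duplicated
#' segments (creating non-unique k-mers), a unimodal GC-dependent
#' fragment rate (scaled Beta density over window GC fraction, peaking in
#' the 40--50\% GC range like the empirically observed coverage bias),
#' breakpoint 3-mer cleavage weights, a nucleosomal fragment-length
#' mixture with modes near 166 and 340 bp, a fetal fraction, and optional
#' whole-chromosome trisomy.
#'
#' @param chromLengths named vector of chromosome lengths (bp).  The
#'   default lays out a 20 Mb toy genome with a small "c21" target
#'   chromosome.
#' @param blockLength length of the i.i.d. base-composition blocks (bp).
#' @param blockGCRange range from which each block's GC probability is
#'   drawn uniformly.
#' @param duplications list of segment copies, each
#'   \code{list(chrom, start, length, targetChrom, targetStart)}; the
#'   source bases overwrite the target region verbatim.
#' @param nFragments number of fragments to draw.
#' @param rateCurve \code{list(peak, concentration)}: the fragment rate
#'   at a position is the Beta(1 + peak * c, 1 + (1 - peak) * c) density
#'   evaluated at the GC fraction of the length-\code{gcWindow} window
#'   anchored there.  \code{concentration = 0} gives a uniform rate.
#' @param gcWindow the true GC window length l (bp).
#' @param motifWeights named vector of relative cleavage weights for
#'   breakpoint 3-mers (unnamed motifs get 1).  The default elevates the
#'   C-rich motifs seen in plasma data.
#' @param lengthMixture \code{list(means, sds, weights, min)} for the
#'   fragment-length mixture.
#' @param fetalLengths \code{list(enabled, mean, sd)}: when enabled,
#'   fetal-origin fragments draw their length from this (shorter) mode.
#' @param fetalFraction fetal fraction f in [0, 1).
#' @param trisomy chromosome with a fetal trisomy, or NA for euploid.
#' @param seed integer seed.
#' @return a \code{SimulationConfig} (a list).
#' @export
simConfig <- function(chromLengths = c(c1 = 6e6, c2 = 5e6, c3 = 4.5e6,
                                       c4 = 3.5e6, c21 = 1e6),
                      blockLength = 20000L,
                      blockGCRange = c(0.32, 0.58),
                      duplications = NULL,
                      nFragments = 5e5,
                      rateCurve = list(peak = 0.45, concentration = 30),
                      gcWindow = 180L,
                      motifWeights = c("C*CC" = 4.5, "C*GG" = 2.5,
                                       "C*CA" = 2.5, "C*TG" = 2.5,
                                       "T*CC" = 2.5, "T*TG" = 2),
                      lengthMixture = list(means = c(166, 340),
                                           sds = c(20, 30),
                                           weights = c(0.85, 0.15),
                                           min = 50),
                      fetalLengths = list(enabled = FALSE, mean = 143,
                                          sd = 15),
                      fetalFraction = 0.10,
                      trisomy = NA_character_,
                      seed = 1L) {
    if (is.null(names(chromLengths)))
        stop("chromLengths must be named")
    if (fetalFraction < 0 || fetalFraction >= 1)
        stop("fetalFraction must be in [0, 1)")
    if (abs(sum(lengthMixture$weights) - 1) > 1e-9)
        stop("length mixture weights must sum to 1")
    if (!is.null(motifWeights)) {
        if (any(motifWeights <= 0))
            stop("motif weights must be positive")
        bad <- setdiff(names(motifWeights), breakpointMotifs())
        if (length(bad))
            stop("unknown motif(s): ", paste(bad, collapse = ", "))
    }
    if (!is.na(trisomy) && !trisomy %in% names(chromLengths))
        stop("trisomy chromosome not in chromLengths")
    structure(list(chromLengths = chromLengths,
                   blockLength = as.integer(blockLength),
                   blockGCRange = blockGCRange,
                   duplications = duplications,
                   nFragments = nFragments, rateCurve = rateCurve,
                   gcWindow = as.integer(gcWindow),
                   motifWeights = motifWeights,
                   lengthMixture = lengthMixture,
                   fetalLengths = fetalLengths,
                   fetalFraction = fetalFraction, trisomy = trisomy,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Simulate a toy genome
#'
#' Bases are drawn i.i.d. within blocks, each block with its own GC
#' probability (G/C and A/T split evenly), then any configured duplicated
#' segments are copied verbatim so that \code{computeUniquePositions}
#' sees genuinely non-unique regions.  Deterministic given the seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{DNAStringSet}.
#' @export
simulateGenome <- function(config) {
    codes <- .withSeed(config$seed, {
        lapply(config$chromLengths, function(L) {
            L <- as.integer(L)
            nb <- ceiling(L / config$blockLength)
            pgc <- stats::runif(nb, config$blockGCRange[1],
                                config$blockGCRange[2])
            p <- rep(pgc, each = config$blockLength)[seq_len(L)]
            isGC <- stats::runif(L) < p
            pick <- stats::runif(L) < 0.5
            ifelse(isGC, ifelse(pick, 1L, 2L),
                   ifelse(pick, 0L, 3L))
        })
    })
    names(codes) <- names(config$chromLengths)
    for (dup in config$duplications) {
        src <- codes[[dup$chrom]]
        if (is.null(src) || dup$start < 1 ||
            dup$start + dup$length - 1 > length(src))
            stop("duplicated segment out of bounds on ", dup$chrom)
        tgt <- dup$targetChrom
        if (is.null(codes[[tgt]]) || dup$targetStart < 1 ||
            dup$targetStart + dup$length - 1 > length(codes[[tgt]]))
            stop("duplication target out of bounds on ", tgt)
        codes[[tgt]][dup$targetStart:(dup$targetStart + dup$length - 1)] <-
            src[dup$start:(dup$start + dup$length - 1)]
    }
    seqs <- vapply(codes, function(v)
        intToUtf8(c(65L, 67L, 71L, 84L)[v + 1L]), character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(config$chromLengths)
    out
}

## shift with NA padding: k > 0 looks ahead, k < 0 looks back
.shift <- function(x, k) {
    L <- length(x)
    if (k == 0L) return(x)
    if (k > 0L) c(x[(k + 1L):L], rep(NA_integer_, k))
    else c(rep(NA_integer_, -k), x[seq_len(L + k)])
}

#' Per-position sampling weights of the fragment generator
#'
#' For every (position, strand) the weight is
#' rate(GC of the strand-oriented l-window) x motif weight of the
#' breakpoint 3-mer x copy factor, where the copy factor is
#' \code{2 (1 - f) + 3 f} on a trisomic target chromosome and 2
#' elsewhere (disomic baseline).  Positions whose window or motif context
#' is undefined get weight 0.  Computing the field once and passing it to
#' \code{\link{simulateFragments}} lets a cohort share it.
#'
#' @param genome \code{DNAStringSet} (from \code{\link{simulateGenome}}
#'   or user FASTA).
#' @param config a \code{\link{simConfig}}.
#' @return an object of class \code{cfSimWeights}.
#' @export
samplingWeights <- function(genome, config) {
    cache <- .genomeCache(genome)
    l <- config$gcWindow
    rc <- config$rateCurve
    a <- 1 + rc$peak * rc$concentration
    b <- 1 + (1 - rc$peak) * rc$concentration
    mw <- rep(1, 64)
    names(mw) <- breakpointMotifs()
    if (!is.null(config$motifWeights))
        mw[names(config$motifWeights)] <- config$motifWeights
    f <- config$fetalFraction
    out <- list()
    for (chrom in names(genome)) {
        cc <- .cacheCodes(cache, chrom)
        L <- length(cc$codes)
        copy <- if (!is.na(config$trisomy) && chrom == config$trisomy)
            (2 * (1 - f) + 3 * f) / 2 else 1
        codes <- cc$codes
        gcp <- cc$gc
        np <- cc$n
        mkW <- function(minus) {
            pos <- seq_len(L)
            if (!minus) {
                okWin <- pos + l - 1L <= L
                lo <- pos
            } else {
                okWin <- pos - l + 1L >= 1L
                lo <- pos - l + 1L
            }
            gc <- rep(NA_real_, L)
            idx <- which(okWin)
            loi <- lo[idx]
            gc[idx] <- gcp[loi + l] - gcp[loi]
            gc[idx][np[loi + l] - np[loi] > 0] <- NA_real_
            if (!minus) {
                mIdx <- 16L * .shift(codes, -2L) + 4L * codes +
                    .shift(codes, 1L) + 1L
            } else {
                mIdx <- 16L * (3L - .shift(codes, 2L)) +
                    4L * (3L - codes) + (3L - .shift(codes, -1L)) + 1L
            }
            rate <- if (rc$concentration == 0) rep(1, L)
                    else stats::dbeta(gc / l, a, b)
            w <- rate * mw[mIdx] * copy
            w[is.na(w)] <- 0
            w
        }
        out[[chrom]] <- list(plus = mkW(FALSE), minus = mkW(TRUE),
                             copy = copy)
    }
    cells <- do.call(rbind, lapply(names(out), function(chrom)
        data.frame(chrom = chrom, strand = c("+", "-"),
                   total = c(sum(out[[chrom]]$plus),
                             sum(out[[chrom]]$minus)),
                   copy = out[[chrom]]$copy,
                   stringsAsFactors = FALSE)))
    if (sum(cells$total) <= 0)
        stop("all sampling weights are zero")
    structure(list(l = l, weights = out, cells = cells,
                   fetalFraction = f, trisomy = config$trisomy),
              class = "cfSimWeights")
}

#' Simulate plasma-like fragments
#'
#' Fragment 5' ends are drawn by multinomial sampling of the
#' (position, strand) weight field (see \code{\link{samplingWeights}});
#' lengths come from the nucleosomal mixture (optionally with a shorter
#' fetal mode) truncated at chromosome ends; mapping quality is set to
#' 70.  Returns the fragments and a \code{SimulationTruth} record with
#' the expected target-chromosome representation (1 + f/2 under trisomy).
#'
#' @param genome \code{DNAStringSet}.
#' @param config a \code{\link{simConfig}}.
#' @param seed seed for fragment sampling (defaults to the config seed).
#' @param weights optional precomputed \code{\link{samplingWeights}}.
#' @param track optional \code{\link{MappabilityTrack}}; when given,
#'   fragments whose aligned k-mer start is not uniquely mappable are
#'   discarded, emulating the upstream removal of multi-mapping reads
#'   from real aligned data.
#' @return list with \code{fragments} (a \code{GRanges}) and
#'   \code{truth}.
#' @export
simulateFragments <- function(genome, config, seed = config$seed,
                              weights = NULL, track = NULL) {
    if (is.null(weights))
        weights <- samplingWeights(genome, config)
    lens <- .seqLengths(genome)
    f <- config$fetalFraction
    lmix <- config$lengthMixture
    .withSeed(seed, {
        cells <- weights$cells
        nPer <- as.integer(stats::rmultinom(1, config$nFragments,
                                            cells$total))
        parts <- vector("list", nrow(cells))
        for (i in seq_len(nrow(cells))) {
            m <- nPer[i]
            if (m == 0L) next
            chrom <- cells$chrom[i]
            minus <- cells$strand[i] == "-"
            w <- if (minus) weights$weights[[chrom]]$minus
                 else weights$weights[[chrom]]$plus
            cw <- cumsum(w)
            tot <- cw[length(cw)]
            pos <- findInterval(stats::runif(m) * tot, cw) + 1L
            ## fetal origin probability; 3f/(2+f) on the trisomic target
            pFetal <- if (!is.na(config$trisomy) &&
                          chrom == config$trisomy) 3 * f / (2 + f) else f
            fetal <- stats::runif(m) < pFetal
            if (config$fetalLengths$enabled) {
                comp <- sample.int(2L, m, replace = TRUE,
                                   prob = lmix$weights)
                len <- round(stats::rnorm(m, lmix$means[comp],
                                          lmix$sds[comp]))
                lenF <- round(stats::rnorm(m, config$fetalLengths$mean,
                                           config$fetalLengths$sd))
                len[fetal] <- lenF[fetal]
            } else {
                comp <- sample.int(2L, m, replace = TRUE,
                                   prob = lmix$weights)
                len <- round(stats::rnorm(m, lmix$means[comp],
                                          lmix$sds[comp]))
            }
            len <- pmax(len, lmix$min)
            L <- lens[[chrom]]
            if (minus) {
                s <- pmax(pos - len + 1L, 1L)
                e <- pos
            } else {
                s <- pos
                e <- pmin(pos + len - 1L, L)
            }
            parts[[i]] <- data.frame(chrom = chrom, start = s, end = e,
                                     strand = if (minus) "-" else "+",
                                     fetal = fetal)
        }
        df <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
        frags <- GRanges(factor(df$chrom, levels = names(lens)),
                         IRanges(df$start, df$end),
                         strand = df$strand,
                         seqlengths = lens)
        mcols(frags)$mapq <- 70L
        mcols(frags)$fetal <- df$fetal
        multimapDropped <- 0L
        if (!is.null(track)) {
            p5 <- .fivePrimeEnds(frags)
            fchrom <- as.character(seqnames(frags))
            minus <- as.character(strand(frags)) == "-"
            kmerStart <- ifelse(minus, p5 - track@k + 1L, p5)
            keep <- logical(length(frags))
            for (chrom in unique(fchrom)) {
                f <- track@flags[[chrom]]
                sel <- fchrom == chrom
                ks <- kmerStart[sel]
                ok <- ks >= 1L & ks <= length(f)
                kp <- logical(sum(sel))
                kp[ok] <- f[ks[ok]]
                keep[sel] <- kp
            }
            multimapDropped <- sum(!keep)
            frags <- frags[keep]
        }
        cellShare <- cells$total / sum(cells$total)
        perChrom <- vapply(split(cellShare, cells$chrom), sum,
                           numeric(1))
        truth <- structure(list(
            config = config, seed = seed,
            multimapDropped = multimapDropped,
            perChromCounts = table(as.character(seqnames(frags))),
            expectedShare = perChrom,
            expectedRepresentation =
                if (!is.na(config$trisomy) && f > 0) 1 + f / 2 else 1),
            class = "SimulationTruth")
        list(fragments = frags, truth = truth)
    })
}

#' Write a simulated dataset to disk
#'
#' FASTA for the genome, BED6 for the fragments (0-based half-open,
#' score = mapping quality) and JSON for the ground truth; all outputs
#' are deterministic given the seeds.
#'
#' @param genome \code{DNAStringSet}.
#' @param frags fragment \code{GRanges}.
#' @param truth a \code{SimulationTruth}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(genome, frags, truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    bed <- data.frame(chrom = as.character(seqnames(frags)),
                      start = start(frags) - 1L, end = end(frags),
                      name = ".", score = mcols(frags)$mapq,
                      strand = as.character(strand(frags)))
    utils::write.table(bed, file.path(dir, "fragments.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    tr <- truth
    tr$perChromCounts <- as.list(tr$perChromCounts)
    tr$config$chromLengths <- as.list(tr$config$chromLengths)
    jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(dir)
}
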