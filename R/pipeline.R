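PROTOCOLS <- c("rm_loess", "mapcorr_loess", "mapcorr_singlepos",
               "mapcorr_singlepos_frag")

#' Build a run configuration
#'
#' Bundles inputs and parameters for \code{\link{runProtocol}}.  Inputs
#' may be in-memory objects or file paths (FASTA genome, BED fragments,
#' BED repeats, bedGraph mappability).  Validation is performed up
#' front: the repeat-removal protocol requires a repeat annotation, the
#' mappability-corrected protocols require a mappability track or a
#' genome to compute one from.
#'
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param fragments fragment \code{GRanges} or BED/SAM/BAM path.
#' @param protocol one of \code{rm_loess}, \code{mapcorr_loess},
#'   \code{mapcorr_singlepos}, \code{mapcorr_singlepos_frag}.
#' @param repeats repeat \code{GRanges} or BED path (rm_loess only).
#' @param mappability \code{MappabilityTrack} or bedGraph path; computed
#'   from the genome when absent.
#' @param binSize bin width (default 50000 bp).
#' @param gcWindowPolicy \code{"fixed"} or \code{"tv-scan"}.
#' @param gcWindow fixed GC window length (default 180 bp).
#' @param stratumMotifs stratum-1 motif set for the fragmentation
#'   protocol.
#' @param k read length for computed mappability (default 50).
#' @param span LOESS span.
#' @param zThreshold Z-score threshold (default 3).
#' @param mappabilityCutoff bins below this mappability are dropped.
#' @param reciprocalMappability apply the 1/mappability factor in the
#'   single-position protocols.
#' @param sampleSize position sample size for single-position fits.
#' @param seed integer seed for all stochastic stages.
#' @param outputDir optional directory for TSV outputs and the log.
#' @return a \code{RunConfig} (a validated list).
#' @export
runConfig <- function(genome, fragments, protocol,
                      repeats = NULL, mappability = NULL,
                      binSize = 50000L,
                      gcWindowPolicy = c("fixed", "tv-scan"),
                      gcWindow = 180L,
                      stratumMotifs = c("C*CC", "C*GG", "C*CA", "C*TG"),
                      k = 50L, span = 0.3, zThreshold = 3,
                      mappabilityCutoff = 0.5,
                      reciprocalMappability = TRUE,
                      sampleSize = 5e6, seed = 1L,
                      outputDir = NULL) {
    protocol <- match.arg(protocol, PROTOCOLS)
    gcWindowPolicy <- match.arg(gcWindowPolicy)
    for (p in list(genome, fragments, repeats, mappability))
        if (is.character(p) && !file.exists(p))
            stop("input file not found: ", p)
    if (protocol == "rm_loess" && is.null(repeats))
        stop("protocol rm_loess requires a repeat annotation")
    structure(list(genome = genome, fragments = fragments,
                   protocol = protocol, repeats = repeats,
                   mappability = mappability,
                   binSize = as.integer(binSize),
                   gcWindowPolicy = gcWindowPolicy,
                   gcWindow = as.integer(gcWindow),
                   stratumMotifs = stratumMotifs, k = as.integer(k),
                   span = span, zThreshold = zThreshold,
                   mappabilityCutoff = mappabilityCutoff,
                   reciprocalMappability = reciprocalMappability,
                   sampleSize = sampleSize, seed = as.integer(seed),
                   outputDir = outputDir),
              class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of \code{\link{runConfig}} (paths
#' for \code{genome}, \code{fragments}, \code{repeats},
#' \code{mappability}).
#'
#' @param path YAML file.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(runConfig, y)
}

.resolveGenome <- function(x) {
    if (is.character(x)) loadFasta(x) else x
}
.resolveFragments <- function(x, genome) {
    if (is.character(x)) readFragments(x, genome = genome) else x
}
.resolveRepeats <- function(x) {
    if (is.character(x)) loadRepeatBed(x) else x
}
.resolveTrack <- function(x, genome, k) {
    if (is.null(x)) computeUniquePositions(genome, k)
    else if (is.character(x)) importMappability(x, genome, k)
    else x
}

#' Run a bias-correction protocol
#'
#' Executes one of the four protocols end to end:
#' \describe{
#'   \item{rm_loess}{repeat removal, binning, LOESS GC correction.}
#'   \item{mapcorr_loess}{binning, reciprocal-mappability correction,
#'     LOESS GC correction of the corrected counts.}
#'   \item{mapcorr_singlepos}{binning, single-position GC correction
#'     with the reciprocal-mappability factor.}
#'   \item{mapcorr_singlepos_frag}{breakpoint-motif stratification, then
#'     per-stratum single-position correction combined by stratum
#'     weights, with the reciprocal-mappability factor.}
#' }
#' The corrected values are stored under the protocol name.  A
#' structured log records each stage with its fragment/bin accounting.
#' When \code{outputDir} is set, the corrected bin table, fit
#' diagnostics and log are written as TSV.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list with \code{bins} (a \code{\link{BinTable}}),
#'   \code{protocol}, \code{gcWindow} (for single-position protocols),
#'   \code{fit} diagnostics and \code{log} (a data.frame).
#' @export
runProtocol <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    log <- list()
    note <- function(stage, ...) {
        log[[length(log) + 1L]] <<- data.frame(
            stage = stage, detail = paste0(...),
            stringsAsFactors = FALSE)
    }
    genome <- .resolveGenome(config$genome)
    frags <- .resolveFragments(config$fragments, genome)
    note("load", length(frags), " fragments, ", length(genome),
         " chromosomes")
    scheme <- binScheme(genome, config$binSize)
    needTrack <- config$protocol != "rm_loess"
    track <- if (needTrack)
        .resolveTrack(config$mappability, genome, config$k)
    fit <- NULL
    gcWin <- NA_integer_

    if (config$protocol == "rm_loess") {
        repeats <- .resolveRepeats(config$repeats)
        n0 <- length(frags)
        frags <- removeRepeatFragments(frags, repeats)
        note("repeat_removal", n0 - length(frags), " of ", n0,
             " fragments removed")
        bins <- assignBins(frags, scheme)
        note("bin", length(binRanges(bins)), " bins; ", bins@dropped,
             " fragments outside bins")
        bins <- addBinAnnotation(bins, genome)
        res <- loessGCCorrect(bins, span = config$span,
                              countColumn = "raw",
                              method = "rm_loess")
        bins <- res$bins
        fit <- res$fit
        note("loess", nrow(fit@table), " occupied GC intervals")
    } else {
        bins <- assignBins(frags, scheme)
        note("bin", length(binRanges(bins)), " bins; ", bins@dropped,
             " fragments outside bins")
        bins <- addBinAnnotation(bins, genome, track)
        bins <- mappabilityCorrect(bins,
                                   cutoff = config$mappabilityCutoff)
        note("mappability", sum(validBins(bins)), " bins at or above ",
             config$mappabilityCutoff, " mappability")
        if (config$protocol == "mapcorr_loess") {
            res <- loessGCCorrect(bins, span = config$span,
                                  countColumn = "mapcorr",
                                  method = "mapcorr_loess")
            bins <- res$bins
            fit <- res$fit
            note("loess", nrow(fit@table), " occupied GC intervals")
        } else {
            gcWin <- config$gcWindow
            if (config$gcWindowPolicy == "tv-scan") {
                curve <- gcWindowScan(frags, genome, track,
                                      seed = config$seed)
                curve <- selectGCWindow(curve)
                gcWin <- curve@selected
                note("tv_scan", "selected GC window ", gcWin, " bp")
            }
            if (config$protocol == "mapcorr_singlepos") {
                strata <- singlePositionFit(frags, genome, track,
                                            l = gcWin,
                                            sampleSize = config$sampleSize,
                                            seed = config$seed,
                                            span = config$span)
                note("singlepos_fit", nrow(strata@strata),
                     " occupied GC strata")
                bins <- singlePositionCorrect(
                    bins, strata, genome, track,
                    reciprocalMappability = config$reciprocalMappability,
                    method = "mapcorr_singlepos",
                    mappabilityCutoff = config$mappabilityCutoff)
                fit <- strata
            } else {
                assignment <- assignStrata(frags, genome,
                                           motifs = config$stratumMotifs)
                note("stratify", sprintf("w1 = %.3f",
                                         assignment@weights[1]))
                bins <- stratifiedCorrect(
                    bins, frags, genome, track, assignment,
                    l = gcWin, sampleSize = config$sampleSize,
                    seed = config$seed,
                    reciprocalMappability = config$reciprocalMappability,
                    method = "mapcorr_singlepos_frag",
                    mappabilityCutoff = config$mappabilityCutoff)
                fit <- attr(bins, "stratumFits")
            }
            note("correct", sum(validBins(bins)), " valid bins")
        }
    }
    logDf <- do.call(rbind, log)
    if (!is.null(config$outputDir)) {
        dir.create(config$outputDir, showWarnings = FALSE,
                   recursive = TRUE)
        exportBinTable(bins, file.path(config$outputDir, "bins.tsv"))
        utils::write.table(logDf,
                           file.path(config$outputDir, "log.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (is(fit, "LoessFit"))
            utils::write.table(fit@table,
                               file.path(config$outputDir,
                                         "loess_fit.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        if (is(fit, "GCStrataTable"))
            utils::write.table(fit@strata,
                               file.path(config$outputDir,
                                         "gc_strata.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
    }
    list(bins = bins, protocol = config$protocol, gcWindow = gcWin,
         fit = fit, log = logDf)
}

#' Evaluate bias-correction protocols over reduced coverage
#'
#' For each sampling proportion and protocol, every sample is
#' subsampled without replacement, corrected, and scored: Z-scores are
#' computed against the euploid reference samples processed in the same
#' (proportion, protocol) cell (leave-one-out for the references
#' themselves), and accuracy and the discriminatory distance are
#' reported.  For the two LOESS protocols the per-sample MAD prediction
#' error is also recorded, allowing the repeat-handling comparison.
#'
#' @param samples named list of fragment \code{GRanges}.
#' @param truth named character vector ("trisomy"/"euploid") per sample.
#' @param referenceIds names of the euploid reference samples (>= 2).
#' @param genome,track shared genome and mappability track.
#' @param repeats repeat \code{GRanges} (needed for rm_loess).
#' @param proportions subsampling proportions (default 1).
#' @param protocols protocols to evaluate.
#' @param target target chromosome (default "c21").
#' @param binSize,gcWindow,span,zThreshold,sampleSize,stratumMotifs,
#'   reciprocalMappability as in \code{\link{runConfig}}.
#' @param seed integer seed; subsampling and fits derive their seeds
#'   from it deterministically.
#' @return list with \code{scores} (per sample x proportion x protocol)
#'   and \code{summary} (accuracy, discriminatory distance, mean MAD).
#' @export
evaluateProtocols <- function(samples, truth, referenceIds, genome,
                              track, repeats = NULL, proportions = 1,
                              protocols = PROTOCOLS, target = "c21",
                              binSize = 50000L, gcWindow = 180L,
                              span = 0.3, zThreshold = 3,
                              sampleSize = 5e6,
                              stratumMotifs = c("C*CC", "C*GG",
                                                "C*CA", "C*TG"),
                              reciprocalMappability = TRUE,
                              seed = 1L) {
    if (length(referenceIds) < 2L)
        stop("need at least 2 reference samples")
    if (is.null(names(samples)) ||
        !all(referenceIds %in% names(samples)))
        stop("samples must be named and include the references")
    if (!all(names(samples) %in% names(truth)))
        stop("truth labels missing for some samples")
    if (any(truth[referenceIds] != "euploid"))
        stop("reference samples must be euploid")
    protocols <- match.arg(protocols, PROTOCOLS, several.ok = TRUE)
    scheme <- binScheme(genome, binSize)
    needSP <- any(protocols %in% c("mapcorr_singlepos",
                                   "mapcorr_singlepos_frag"))
    model <- if (needSP)
        binPositionModel(genome, track, scheme, gcWindow,
                         motifs = if ("mapcorr_singlepos_frag" %in%
                                      protocols) stratumMotifs)
    scores <- list()
    madRows <- list()
    for (pi in seq_along(proportions)) {
        prop <- proportions[pi]
        sub <- lapply(seq_along(samples), function(si)
            subsampleFragments(samples[[si]], prop,
                               seed = seed + 1000L * pi + si))
        names(sub) <- names(samples)
        for (protocol in protocols) {
            ps <- lapply(names(sub), function(id) {
                frags <- sub[[id]]
                if (protocol == "rm_loess") {
                    fr <- removeRepeatFragments(frags, repeats)
                    bins <- addBinAnnotation(assignBins(fr, scheme),
                                             genome)
                    res <- loessGCCorrect(bins, span = span,
                                          countColumn = "raw",
                                          method = protocol)
                    counts <- rawCounts(res$bins)
                    mad <- madError(
                        counts[!is.na(res$fit@predictions)],
                        res$fit@predictions[
                            !is.na(res$fit@predictions)])
                    list(bins = res$bins, mad = mad)
                } else {
                    bins <- addBinAnnotation(assignBins(frags, scheme),
                                             genome, track)
                    bins <- mappabilityCorrect(bins)
                    if (protocol == "mapcorr_loess") {
                        res <- loessGCCorrect(bins, span = span,
                                              countColumn = "mapcorr",
                                              method = protocol)
                        counts <- correctedCounts(res$bins, "mapcorr")
                        ok <- !is.na(res$fit@predictions) &
                            !is.na(counts)
                        mad <- madError(counts[ok],
                                        res$fit@predictions[ok])
                        list(bins = res$bins, mad = mad)
                    } else if (protocol == "mapcorr_singlepos") {
                        strata <- singlePositionFit(
                            frags, genome, track, l = gcWindow,
                            sampleSize = sampleSize,
                            seed = seed + 7L * pi, span = span)
                        bins <- singlePositionCorrect(
                            bins, strata, genome, track,
                            reciprocalMappability =
                                reciprocalMappability,
                            model = model, method = protocol)
                        list(bins = bins, mad = NA_real_)
                    } else {
                        assignment <- assignStrata(
                            frags, genome, motifs = stratumMotifs)
                        bins <- stratifiedCorrect(
                            bins, frags, genome, track, assignment,
                            l = gcWindow, sampleSize = sampleSize,
                            seed = seed + 7L * pi,
                            reciprocalMappability =
                                reciprocalMappability,
                            model = model, method = protocol)
                        list(bins = bins, mad = NA_real_)
                    }
                }
            })
            names(ps) <- names(sub)
            p <- vapply(ps, function(x)
                chromProportion(x$bins, target, method = protocol),
                numeric(1))
            ## every sample, reference or not, is standardized against
            ## the full reference set (the reference samples therefore
            ## contribute to their own mean and sd)
            z <- vapply(names(p), function(id)
                zScore(p[[id]], unname(p[referenceIds]),
                       threshold = zThreshold)$z, numeric(1))
            call <- ifelse(z > zThreshold, "trisomy", "euploid")
            scores[[length(scores) + 1L]] <- data.frame(
                proportion = prop, protocol = protocol,
                sample = names(p), p = unname(p), z = unname(z),
                call = call, truth = unname(truth[names(p)]),
                stringsAsFactors = FALSE)
            madRows[[length(madRows) + 1L]] <- data.frame(
                proportion = prop, protocol = protocol,
                meanMAD = mean(vapply(ps, `[[`, numeric(1), "mad")),
                stringsAsFactors = FALSE)
        }
    }
    scoresDf <- do.call(rbind, scores)
    summary <- do.call(rbind, lapply(split(
        scoresDf, list(scoresDf$proportion, scoresDf$protocol),
        drop = TRUE), function(d) {
            zN <- d$z[d$truth == "euploid"]
            zT <- d$z[d$truth == "trisomy"]
            data.frame(proportion = d$proportion[1],
                       protocol = d$protocol[1],
                       accuracy = callAccuracy(d$call, d$truth),
                       discriminatoryDistance =
                           if (length(zN) && length(zT))
                               discriminatoryDistance(zN, zT)
                           else NA_real_,
                       stringsAsFactors = FALSE)
        }))
    rownames(summary) <- NULL
    mad <- do.call(rbind, madRows)
    summary <- merge(summary, mad,
                     by = c("proportion", "protocol"), sort = FALSE)
    list(scores = scoresDf, summary = summary)
}
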