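#' Chromosome proportion of corrected bin values
#'
#' The target chromosome's summed corrected bin values divided by the
#' sum over all chromosomes except chrY, restricted to valid bins.  This
#' is the molecular-counting statistic underlying the trisomy test.
#'
#' @param bins a \code{\link{BinTable}} with corrected values.
#' @param target target chromosome name (e.g. "chr21").
#' @param method which corrected values to use; defaults to the last
#'   stored correction.
#' @return the proportion (a number in [0, 1]).
#' @export
chromProportion <- function(bins, target,
                            method = utils::tail(correctedMethods(bins), 1)) {
    if (!length(method))
        stop("no corrected values present")
    vals <- correctedCounts(bins, method)
    chrom <- as.character(seqnames(bins@bins))
    if (!target %in% chrom)
        stop("target chromosome ", target, " not in bin table")
    use <- validBins(bins) & analysisBins(bins) & !is.na(vals) &
        !.isChrY(chrom)
    denom <- sum(vals[use])
    if (denom <= 0)
        stop("zero denominator: no corrected mass outside chrY")
    sum(vals[use & chrom == target]) / denom
}

#' Z-score test for chromosomal over-representation
#'
#' Standardizes a sample's chromosome proportion against a reference set
#' of (assumed euploid) samples: z = (p - mean(ref)) / sd(ref), with the
#' sample standard deviation (n - 1 denominator).  Diploidy is rejected
#' when z strictly exceeds the threshold (default 3, i.e. beyond the
#' 99.9th percentile of the reference distribution under normality).
#'
#' @param p the sample's chromosome proportion.
#' @param reference numeric vector of reference proportions (length >= 2).
#' @param threshold rejection threshold (default 3).
#' @return list with \code{z}, \code{call} ("trisomy" or "euploid") and
#'   \code{threshold}.
#' @examples
#' zScore(0.017, c(0.013, 0.014, 0.015))  # z = 3, call euploid (strict)
#' @export
zScore <- function(p, reference, threshold = 3) {
    if (length(reference) < 2L)
        stop("need at least 2 reference samples")
    sdr <- stats::sd(reference)
    if (!is.finite(sdr) || sdr == 0)
        stop("degenerate reference: zero standard deviation")
    z <- (p - mean(reference)) / sdr
    list(z = z, call = if (z > threshold) "trisomy" else "euploid",
         threshold = threshold)
}

#' Discriminatory distance between trisomy and euploid Z-scores
#'
#' The 5th percentile of the trisomy Z-scores minus the 95th percentile
#' of the euploid Z-scores (linear-interpolation quantiles).  Positive
#' values mean the two groups are separated; negative values occur when
#' the distributions overlap.
#'
#' @param zNormals euploid Z-scores.
#' @param zTrisomies trisomy Z-scores.
#' @return the discriminatory distance.
#' @export
discriminatoryDistance <- function(zNormals, zTrisomies) {
    if (!length(zNormals) || !length(zTrisomies))
        stop("both groups must be non-empty")
    unname(stats::quantile(zTrisomies, 0.05, type = 7) -
           stats::quantile(zNormals, 0.95, type = 7))
}

#' Accuracy of trisomy calls
#'
#' @param calls character vector of calls ("trisomy"/"euploid").
#' @param truth character vector of true karyotype labels, aligned with
#'   \code{calls}.
#' @return fraction of correct calls.
#' @export
callAccuracy <- function(calls, truth) {
    if (length(calls) != length(truth))
        stop("calls and truth must align")
    if (length(calls) == 0L)
        stop("empty input")
    mean(calls == truth)
}

#' Reference-free detection via pairwise Welch t-tests
#'
#' Within a single sample, each chromosome's corrected bin values are
#' compared to every other chromosome with a one-sided Welch t-test
#' (alternative: the row chromosome is over-represented).  A chromosome
#' is called over-represented iff its minimum t over all comparisons
#' exceeds the one-sided critical value at the Bonferroni-adjusted level
#' \code{alphaBase / (k (k - 1))} for k chromosomes, so even its closest
#' competitor is significantly below it.
#'
#' @param bins a \code{\link{BinTable}} with corrected values.
#' @param method which corrected values to use.
#' @param chromosomes chromosomes to test (default: all non-chrY
#'   chromosomes in the table).
#' @param alphaBase base significance level (default 0.001).
#' @return data.frame with per-chromosome \code{min_t}, \code{df} and
#'   \code{critical} at the minimising comparison, and \code{call}.
#' @export
welchPairwiseMinT <- function(bins, method = utils::tail(
                                  correctedMethods(bins), 1),
                              chromosomes = NULL, alphaBase = 0.001) {
    vals <- correctedCounts(bins, method)
    chrom <- as.character(seqnames(bins@bins))
    use <- validBins(bins) & !is.na(vals) & !.isChrY(chrom)
    if (is.null(chromosomes))
        chromosomes <- unique(chrom[use])
    groups <- lapply(chromosomes, function(ch) vals[use & chrom == ch])
    names(groups) <- chromosomes
    nbin <- lengths(groups)
    if (any(nbin < 2L))
        stop("chromosome(s) with fewer than 2 valid bins: ",
             paste(chromosomes[nbin < 2L], collapse = ", "))
    k <- length(chromosomes)
    if (k < 2L)
        stop("need at least 2 chromosomes")
    alphaAdj <- alphaBase / (k * (k - 1))
    mu <- vapply(groups, mean, numeric(1))
    v <- vapply(groups, stats::var, numeric(1))
    n <- nbin
    out <- data.frame(chrom = chromosomes, min_t = NA_real_,
                      df = NA_real_, critical = NA_real_,
                      call = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
        tij <- dfij <- numeric(0)
        for (j in seq_len(k)) {
            if (j == i) next
            se2 <- v[i] / n[i] + v[j] / n[j]
            t <- (mu[i] - mu[j]) / sqrt(se2)
            df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                           (v[j] / n[j])^2 / (n[j] - 1))
            tij <- c(tij, t)
            dfij <- c(dfij, df)
        }
        jmin <- which.min(tij)
        crit <- stats::qt(1 - alphaAdj, dfij[jmin])
        out$min_t[i] <- tij[jmin]
        out$df[i] <- dfij[jmin]
        out$critical[i] <- crit
        ## called only when every comparison clears its own critical value
        out$call[i] <- all(tij > stats::qt(1 - alphaAdj, dfij))
    }
    out
}
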