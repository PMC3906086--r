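#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

#' MappabilityTrack: per-base k-mer uniqueness flags
#'
#' Per-chromosome logical vectors flagging, for every possible read start
#' position, whether the length-\code{k} sequence beginning there occurs
#' exactly once in the genome when both strands are considered.  Position
#' \code{x} (1-based) is defined for \code{x <= length - k + 1}.
#'
#' @slot k read length (bp) used to assess uniqueness.
#' @slot flags named list of logical vectors, one per chromosome, of length
#'   \code{chromosome length - k + 1}.
#' @slot provenance \code{"computed"} (exact k-mer matching on the loaded
#'   genome) or \code{"imported"} (external track, e.g. aligner-derived).
#' @exportClass MappabilityTrack
setClass("MappabilityTrack",
    representation(k = "integer", flags = "list", provenance = "character"))

setValidity("MappabilityTrack", function(object) {
    msg <- NULL
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "k must be a single positive integer")
    if (is.null(names(object@flags)) || anyDuplicated(names(object@flags)))
        msg <- c(msg, "flags must be a uniquely named list")
    if (!all(vapply(object@flags, is.logical, logical(1))))
        msg <- c(msg, "flags must contain logical vectors")
    if (!object@provenance %in% c("computed", "imported"))
        msg <- c(msg, "provenance must be 'computed' or 'imported'")
    if (is.null(msg)) TRUE else msg
})

#' BinTable: fixed-width genomic windows with counts and corrections
#'
#' Wraps a \code{GRanges} of non-overlapping, full-width bins tiling each
#' chromosome prefix.  Metadata columns carry the raw fragment count
#' (\code{raw_count}), GC fraction (\code{gc}), mappability
#' (\code{mappability}), a \code{valid} flag (bins failing N-content or
#' mappability filters are excluded downstream), an \code{analysis} flag
#' (chrY bins are excluded from chromosome-proportion denominators), and
#' per-method corrected values in columns named \code{corrected.<method>}.
#'
#' @slot bins \code{GRanges} of bins with the metadata columns above.
#' @slot binSize bin width in bp.
#' @slot dropped number of fragments whose 5' end fell outside the binned
#'   region (trailing partial bins are not kept).
#' @exportClass BinTable
setClass("BinTable",
    representation(bins = "GRanges", binSize = "integer",
                   dropped = "integer"))

setValidity("BinTable", function(object) {
    msg <- NULL
    mc <- mcols(object@bins)
    if (!"raw_count" %in% colnames(mc))
        msg <- c(msg, "bins must carry a raw_count column")
    else if (any(mc$raw_count < 0))
        msg <- c(msg, "raw counts must be non-negative")
    if (length(object@bins) && !all(width(object@bins) == object@binSize))
        msg <- c(msg, "all bins must have width binSize")
    if (is.null(msg)) TRUE else msg
})

#' GCStrataTable: the single-position model's per-stratum rates
#'
#' Positions are stratified by the integer G+C count of the fixed-length
#' window starting at the position (strand-oriented), giving
#' \code{windowLength + 1} possible strata.  For each occupied stratum the
#' table records the number of sampled positions, the number of fragments
#' starting at those positions, the raw mean fragment rate and the
#' smoothed rate.  \code{smoothAll} carries a smoothed prediction for every
#' stratum 0..l, including empty ones, so per-position predictions are
#' always defined.
#'
#' @slot windowLength GC window length l (bp).
#' @slot strata data.frame with columns \code{gc}, \code{n},
#'   \code{fragments}, \code{rate}, \code{smooth} (occupied strata only).
#' @slot smoothAll numeric vector of length \code{windowLength + 1}:
#'   smoothed rate for every stratum, clamped at 0.
#' @slot sampleInfo list describing the position sample (count, seed).
#' @exportClass GCStrataTable
setClass("GCStrataTable",
    representation(windowLength = "integer", strata = "data.frame",
                   smoothAll = "numeric", sampleInfo = "list"))

setValidity("GCStrataTable", function(object) {
    msg <- NULL
    st <- object@strata
    need <- c("gc", "n", "fragments", "rate", "smooth")
    if (!all(need %in% colnames(st)))
        msg <- c(msg, "strata must have gc, n, fragments, rate, smooth")
    else {
        if (any(st$n <= 0))
            msg <- c(msg, "occupied strata must have n > 0")
        if (any(st$smooth < 0))
            msg <- c(msg, "smoothed rates must be non-negative")
    }
    if (length(object@smoothAll) != object@windowLength + 1L)
        msg <- c(msg, "smoothAll must have windowLength + 1 entries")
    if (is.null(msg)) TRUE else msg
})

#' TVScoreCurve: TV score as a function of GC window length
#'
#' @slot windowLengths window lengths (bp) scanned.
#' @slot scores TV score for each length, in [0, 1].
#' @slot selected chosen window length (NA until selection).
#' @exportClass TVScoreCurve
setClass("TVScoreCurve",
    representation(windowLengths = "integer", scores = "numeric",
                   selected = "integer"))

setValidity("TVScoreCurve", function(object) {
    msg <- NULL
    if (length(object@windowLengths) != length(object@scores))
        msg <- c(msg, "lengths and scores must align")
    ok <- !is.na(object@scores)
    if (any(object@scores[ok] < -1e-12 | object@scores[ok] > 1 + 1e-12))
        msg <- c(msg, "TV scores must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' PositionalBaseProfile: base composition around fragment termini
#'
#' @slot end which terminus the profile is anchored on: "5p" or "3p".
#' @slot offsets integer offsets relative to the terminus (0 = terminal
#'   fragment base), in fragment-strand orientation.
#' @slot proportions matrix (offsets x A,C,G,T) of base proportions.
#' @slot counts number of fragment contexts contributing at each offset.
#' @exportClass PositionalBaseProfile
setClass("PositionalBaseProfile",
    representation(end = "character", offsets = "integer",
                   proportions = "matrix", counts = "integer"))

setValidity("PositionalBaseProfile", function(object) {
    msg <- NULL
    if (!object@end %in% c("5p", "3p"))
        msg <- c(msg, "end must be '5p' or '3p'")
    pr <- object@proportions
    if (nrow(pr) != length(object@offsets) || ncol(pr) != 4L)
        msg <- c(msg, "proportions must be offsets x 4")
    used <- object@counts > 0L
    if (any(abs(rowSums(pr[used, , drop = FALSE]) - 1) > 1e-9))
        msg <- c(msg, "proportions must sum to 1 at each used offset")
    if (is.null(msg)) TRUE else msg
})

#' MotifFrequencyTable: breakpoint 3-mer counts per strand
#'
#' Counts of the 64 breakpoint 3-mers (bases at offsets -2, 0, +1 relative
#' to the 5' fragment start, read-strand orientation, rendered "X*YZ" with
#' the wildcard at -1) for plus- and minus-strand fragments separately.
#'
#' @slot counts 64 x 2 integer matrix (motifs x plus/minus).
#' @slot excluded fragments skipped per strand because the reference
#'   context contained N or fell out of bounds.
#' @exportClass MotifFrequencyTable
setClass("MotifFrequencyTable",
    representation(counts = "matrix", excluded = "integer"))

setValidity("MotifFrequencyTable", function(object) {
    msg <- NULL
    if (nrow(object@counts) != 64L || ncol(object@counts) != 2L)
        msg <- c(msg, "counts must be a 64 x 2 matrix")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' StratumAssignment: two-class fragmentation stratification
#'
#' Fragments are split into stratum 1 (5' breakpoint 3-mer in a fixed motif
#' set) and stratum 2 (all other motifs).  The stratum is a property of the
#' mapped position and strand: it is read from the reference context, not
#' from the read bases.
#'
#' @slot motifs the stratum-1 motif set (e.g. C*CC, C*GG, C*CA, C*TG).
#' @slot stratum integer vector (1, 2 or NA) per fragment.
#' @slot weights sample-wide stratum proportions (w1, w2), summing to 1.
#' @exportClass StratumAssignment
setClass("StratumAssignment",
    representation(motifs = "character", stratum = "integer",
                   weights = "numeric"))

setValidity("StratumAssignment", function(object) {
    msg <- NULL
    if (!all(object@motifs %in% breakpointMotifs()))
        msg <- c(msg, "motifs must be valid breakpoint 3-mers")
    if (length(object@weights) != 2L ||
        abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must be two proportions summing to 1")
    if (!all(object@stratum %in% c(1L, 2L, NA_integer_)))
        msg <- c(msg, "stratum must be 1, 2 or NA")
    if (is.null(msg)) TRUE else msg
})

#' LoessFit: binned LOESS GC model summary
#'
#' @slot span LOESS span used.
#' @slot table data.frame of (GC percent interval midpoint, mean bin
#'   count, fitted value) for the occupied 1 percent GC intervals.
#' @slot predictions per-bin predicted count (NA for bins not assessed).
#' @exportClass LoessFit
setClass("LoessFit",
    representation(span = "numeric", table = "data.frame",
                   predictions = "numeric"))

## ---- show methods ----

setMethod("show", "MappabilityTrack", function(object) {
    cat("MappabilityTrack (", object@provenance, "), k = ", object@k,
        "\n", sep = "")
    n <- vapply(object@flags, length, integer(1))
    u <- vapply(object@flags, sum, integer(1))
    cat("  ", length(n), " chromosome(s); unique fraction ",
        sprintf("%.3f", sum(u) / max(1, sum(n))), "\n", sep = "")
})

setMethod("show", "BinTable", function(object) {
    cat("BinTable: ", length(object@bins), " bins of ", object@binSize,
        " bp\n", sep = "")
    mc <- mcols(object@bins)
    corr <- grep("^corrected\\.", colnames(mc), value = TRUE)
    if ("valid" %in% colnames(mc))
        cat("  valid bins: ", sum(mc$valid), "\n", sep = "")
    if (length(corr))
        cat("  corrections: ",
            paste(sub("^corrected\\.", "", corr), collapse = ", "),
            "\n", sep = "")
    if (object@dropped > 0L)
        cat("  fragments outside binned region: ", object@dropped, "\n",
            sep = "")
})

setMethod("show", "GCStrataTable", function(object) {
    cat("GCStrataTable: window ", object@windowLength, " bp, ",
        nrow(object@strata), " occupied strata\n", sep = "")
    cat("  positions sampled: ", object@sampleInfo$nPositions,
        "; fragments at sampled positions: ",
        sum(object@strata$fragments), "\n", sep = "")
})

setMethod("show", "TVScoreCurve", function(object) {
    cat("TVScoreCurve over ", length(object@windowLengths),
        " window lengths [", min(object@windowLengths), ", ",
        max(object@windowLengths), "] bp\n", sep = "")
    if (!is.na(object@selected))
        cat("  selected GC window: ", object@selected, " bp\n", sep = "")
})

setMethod("show", "PositionalBaseProfile", function(object) {
    cat("PositionalBaseProfile (", object@end, " end), offsets ",
        min(object@offsets), "..", max(object@offsets), ", ",
        max(object@counts), " fragments\n", sep = "")
})

setMethod("show", "MotifFrequencyTable", function(object) {
    tot <- colSums(object@counts)
    cat("MotifFrequencyTable: 64 breakpoint 3-mers\n")
    cat("  fragments: +", tot[1], " / -", tot[2], "; excluded: ",
        sum(object@excluded), "\n", sep = "")
    p <- rowSums(object@counts) / max(1, sum(object@counts))
    top <- head(order(p, decreasing = TRUE), 5)
    cat("  top motifs:", paste(sprintf("%s (%.1f%%)",
        rownames(object@counts)[top], 100 * p[top]), collapse = ", "),
        "\n")
})

setMethod("show", "StratumAssignment", function(object) {
    cat("StratumAssignment: stratum 1 = {",
        paste(object@motifs, collapse = ", "), "}\n", sep = "")
    cat(sprintf("  weights: w1 = %.3f, w2 = %.3f (%d fragments)\n",
        object@weights[1], object@weights[2], length(object@stratum)))
})

setMethod("show", "LoessFit", function(object) {
    cat("LoessFit: span ", object@span, ", ", nrow(object@table),
        " occupied GC intervals\n", sep = "")
})
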