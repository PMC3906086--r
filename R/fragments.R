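#' Read aligned fragment records from BED or SAM/BAM
#'
#' Fragments are returned as a \code{GRanges} (1-based, closed intervals)
#' with strand and a \code{mapq} metadata column.  For SAM/BAM input,
#' unmapped, secondary and duplicate-flagged records are skipped and the
#' skip counts reported via a message and the \code{"skipped"} attribute.
#' The strand-aware 5' end is the leftmost base for + fragments and the
#' rightmost base for - fragments.
#'
#' @param path input file (.bed, .sam or .bam; format guessed from the
#'   extension unless given).
#' @param genome optional \code{DNAStringSet}; when supplied, records on
#'   chromosomes absent from the genome raise an error.
#' @param format "auto", "bed", "sam" or "bam".
#' @return \code{GRanges} with \code{mapq} metadata column.
#' @export
readFragments <- function(path, genome = NULL,
                          format = c("auto", "bed", "sam", "bam")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                         stop("cannot guess format from extension: ", path))
    }
    if (format == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        mapq <- if (!is.null(gr$score)) as.integer(gr$score)
                else rep(NA_integer_, length(gr))
        frags <- GRanges(seqnames(gr),
                         IRanges(start(gr), end(gr)),
                         strand = strand(gr))
        skipped <- c(unmapped = 0L, secondary = 0L, duplicate = 0L)
    } else {
        bam <- path
        if (format == "sam")
            bam <- Rsamtools::asBam(path,
                                    destination = tempfile(),
                                    indexDestination = FALSE)
        res <- Rsamtools::scanBam(bam,
            param = Rsamtools::ScanBamParam(
                what = c("rname", "pos", "strand", "qwidth", "mapq",
                         "flag")))[[1]]
        flag <- res$flag
        unmapped <- bitwAnd(flag, 4L) != 0L
        secondary <- bitwAnd(flag, 256L) != 0L
        duplicate <- bitwAnd(flag, 1024L) != 0L
        drop <- unmapped | secondary | duplicate
        skipped <- c(unmapped = sum(unmapped),
                     secondary = sum(secondary & !unmapped),
                     duplicate = sum(duplicate & !unmapped & !secondary))
        if (any(drop))
            message("readFragments: skipped ", sum(drop), " record(s) (",
                    paste(names(skipped), skipped, sep = "=",
                          collapse = ", "), ")")
        keep <- which(!drop)
        frags <- GRanges(as.character(res$rname)[keep],
                         IRanges(start = res$pos[keep],
                                 width = res$qwidth[keep]),
                         strand = res$strand[keep])
        mapq <- as.integer(res$mapq)[keep]
    }
    if (any(!as.character(strand(frags)) %in% c("+", "-")))
        stop("fragments must have + or - strand")
    mcols(frags)$mapq <- mapq
    if (!is.null(genome))
        .checkChromsKnown(seqnames(frags), names(genome))
    attr(frags, "skipped") <- skipped
    frags
}

#' Build a fixed-width bin scheme
#'
#' Tiles each chromosome prefix with non-overlapping bins of
#' \code{binSize} bp; trailing partial bins are dropped so that all bins
#' are directly comparable.
#'
#' @param genome a \code{DNAStringSet} (or a named vector of chromosome
#'   lengths).
#' @param binSize bin width in bp (default 50000, the width in common use
#'   for NIPT coverage analysis).
#' @return \code{GRanges} of full-width bins.
#' @export
binScheme <- function(genome, binSize = 50000L) {
    binSize <- as.integer(binSize)
    if (binSize < 1L)
        stop("binSize must be positive")
    lens <- if (is.numeric(genome)) genome else .seqLengths(genome)
    if (is.null(names(lens)))
        stop("chromosome lengths must be named")
    nb <- lens %/% binSize
    if (all(nb == 0L))
        stop("no chromosome is as long as one bin")
    chrom <- rep(names(lens), nb)
    idx <- unlist(lapply(nb, seq_len), use.names = FALSE)
    GRanges(factor(chrom, levels = names(lens)),
            IRanges(start = idx * binSize - binSize + 1L,
                    width = binSize))
}

#' Count fragment 5' ends per bin
#'
#' Each fragment increments exactly the bin containing its strand-aware 5'
#' end.  Fragments whose 5' end falls past the last full bin of a
#' chromosome are dropped and reported in the \code{dropped} slot.
#'
#' @param frags \code{GRanges} of fragments.
#' @param scheme bin scheme from \code{\link{binScheme}}.
#' @return a \code{\link{BinTable}} with raw counts.
#' @export
assignBins <- function(frags, scheme) {
    binSize <- unique(width(scheme))
    if (length(binSize) != 1L)
        stop("scheme must have constant bin width")
    chroms <- as.character(seqnames(scheme))
    .checkChromsKnown(seqnames(frags), unique(chroms))
    p5 <- .fivePrimeEnds(frags)
    fchrom <- as.character(seqnames(frags))
    counts <- integer(length(scheme))
    dropped <- 0L
    for (chrom in unique(chroms)) {
        idx <- which(chroms == chrom)
        nb <- length(idx)
        fp <- p5[fchrom == chrom]
        b <- (fp - 1L) %/% binSize + 1L
        inside <- b >= 1L & b <= nb
        dropped <- dropped + sum(!inside)
        counts[idx] <- counts[idx] + tabulate(b[inside], nbins = nb)
    }
    bins <- scheme
    mcols(bins) <- NULL
    mcols(bins)$raw_count <- counts
    mcols(bins)$analysis <- !.isChrY(chroms)
    new("BinTable", bins = bins, binSize = as.integer(binSize),
        dropped = as.integer(dropped))
}

#' Discard fragments whose 5' end lies in a repeat interval
#'
#' Repeat handling by hard filtering: a fragment is removed iff its
#' strand-aware 5' end falls inside an annotated repeat.  With
#' \code{overlap = "any"}, any overlap between the fragment and a repeat
#' removes it instead.
#'
#' @param frags \code{GRanges} of fragments.
#' @param repeats \code{GRanges} of repeat intervals (see
#'   \code{\link{loadRepeatBed}}).
#' @param overlap "end" (default; 5'-end containment) or "any".
#' @return the surviving fragments, unchanged.
#' @export
removeRepeatFragments <- function(frags, repeats,
                                  overlap = c("end", "any")) {
    overlap <- match.arg(overlap)
    if (overlap == "any") {
        hit <- IRanges::overlapsAny(frags, repeats, ignore.strand = TRUE)
    } else {
        p5 <- .fivePrimeEnds(frags)
        ends <- GRanges(seqnames(frags), IRanges(p5, p5))
        hit <- IRanges::overlapsAny(ends, repeats, ignore.strand = TRUE)
    }
    frags[!hit]
}

#' Mappability correction of bin counts
#'
#' Bin counts are multiplied by the reciprocal of the bin's mappability.
#' Bins with mappability below \code{cutoff} (default 0.5, i.e. less than
#' 50\% unique sites) are invalidated rather than corrected, to prevent
#' over-correction.
#'
#' @param bins a \code{\link{BinTable}} whose \code{mappability} column is
#'   populated (see \code{\link{addBinAnnotation}}).
#' @param cutoff minimum mappability for a bin to be corrected.
#' @return the \code{BinTable} with a \code{corrected.mapcorr} column.
#' @export
mappabilityCorrect <- function(bins, cutoff = 0.5) {
    mc <- mcols(bins@bins)
    if (!"mappability" %in% colnames(mc))
        stop("mappability not populated; run addBinAnnotation() first")
    m <- mc$mappability
    valid <- if ("valid" %in% colnames(mc)) mc$valid else rep(TRUE, length(m))
    ok <- m >= cutoff
    corrected <- rep(NA_real_, length(m))
    corrected[valid & ok] <- mc$raw_count[valid & ok] / m[valid & ok]
    mcols(bins@bins)$valid <- valid & ok
    mcols(bins@bins)$corrected.mapcorr <- corrected
    validObject(bins)
    bins
}

#' Annotate a BinTable with GC and mappability
#'
#' Convenience step filling the \code{gc}, \code{mappability} and
#' \code{valid} columns from the genome and a mappability track.
#'
#' @param bins a \code{\link{BinTable}}.
#' @param genome \code{DNAStringSet}.
#' @param track \code{\link{MappabilityTrack}} (optional).
#' @param nMax maximum N fraction for a bin to stay valid.
#' @return the annotated \code{BinTable}.
#' @export
addBinAnnotation <- function(bins, genome, track = NULL, nMax = 0.1) {
    gc <- windowGC(genome, bins@bins, nMax = nMax)
    mcols(bins@bins)$gc <- as.numeric(gc)
    mcols(bins@bins)$valid <- attr(gc, "valid")
    if (!is.null(track))
        mcols(bins@bins)$mappability <- windowMappability(track, bins@bins)
    bins
}

#' Subsample fragments without replacement
#'
#' Draws exactly \code{round(proportion * N)} fragments uniformly at
#' random without replacement, deterministically for a given seed; used to
#' emulate lower sequencing depth.
#'
#' @param frags \code{GRanges} of fragments.
#' @param proportion fraction in (0, 1].
#' @param seed integer seed.
#' @return the subsampled \code{GRanges}.
#' @export
subsampleFragments <- function(frags, proportion, seed = 1L) {
    if (!is.numeric(proportion) || length(proportion) != 1L ||
        proportion <= 0 || proportion > 1)
        stop("proportion must be in (0, 1]")
    n <- length(frags)
    size <- round(proportion * n)
    if (size >= n) return(frags)
    idx <- .withSeed(seed, sample.int(n, size))
    frags[sort(idx)]
}

## ---- BinTable accessors ----

#' BinTable accessors
#'
#' @param x a \code{\link{BinTable}}.
#' @param method correction name, e.g. \code{"mapcorr"}, \code{"loess"},
#'   \code{"singlepos"}; see \code{correctedMethods}.
#' @name BinTable-accessors
NULL

#' @rdname BinTable-accessors
#' @export
binRanges <- function(x) x@bins

#' @rdname BinTable-accessors
#' @export
rawCounts <- function(x) mcols(x@bins)$raw_count

#' @rdname BinTable-accessors
#' @export
binGC <- function(x) mcols(x@bins)$gc

#' @rdname BinTable-accessors
#' @export
binMappability <- function(x) mcols(x@bins)$mappability

#' @rdname BinTable-accessors
#' @export
validBins <- function(x) {
    v <- mcols(x@bins)$valid
    if (is.null(v)) rep(TRUE, length(x@bins)) else v
}

#' @rdname BinTable-accessors
#' @export
analysisBins <- function(x) {
    a <- mcols(x@bins)$analysis
    if (is.null(a)) rep(TRUE, length(x@bins)) else a
}

#' @rdname BinTable-accessors
#' @export
correctedMethods <- function(x) {
    sub("^corrected\\.", "",
        grep("^corrected\\.", colnames(mcols(x@bins)), value = TRUE))
}

#' @rdname BinTable-accessors
#' @export
correctedCounts <- function(x, method) {
    col <- paste0("corrected.", method)
    if (!col %in% colnames(mcols(x@bins)))
        stop("no corrected values for method '", method, "'")
    mcols(x@bins)[[col]]
}

#' Export / import a BinTable as TSV
#'
#' Columns: chrom, start (0-based), end, raw_count, gc, mappability,
#' valid, analysis and one \code{corrected:<method>} column per stored
#' correction.
#'
#' @param x a \code{\link{BinTable}} (for export).
#' @param path TSV file path.
#' @return \code{exportBinTable} returns the path invisibly;
#'   \code{importBinTable} a \code{BinTable}.
#' @export
exportBinTable <- function(x, path) {
    mc <- as.data.frame(mcols(x@bins))
    corr <- grep("^corrected\\.", colnames(mc))
    colnames(mc) <- sub("^corrected\\.", "corrected:", colnames(mc))
    df <- data.frame(chrom = as.character(seqnames(x@bins)),
                     start = start(x@bins) - 1L,
                     end = end(x@bins), mc, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname exportBinTable
#' @export
importBinTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mc <- df[, setdiff(colnames(df), c("chrom", "start", "end")),
             drop = FALSE]
    colnames(mc) <- sub("^corrected:", "corrected.", colnames(mc))
    mcols(gr) <- mc
    new("BinTable", bins = gr,
        binSize = as.integer(unique(width(gr))[1]),
        dropped = 0L)
}
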