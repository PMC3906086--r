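#' Load a reference genome from FASTA
#'
#' Sequences are upper-cased and IUPAC ambiguity codes other than N are
#' converted to N (a message reports how many bases were converted), so
#' that downstream code only ever sees the alphabet A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link[Biostrings]{DNAStringSet}} with unique names.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtR"), fa)
#' g <- loadFasta(fa)  # stored as ACGTN
#' @export
loadFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    g <- Biostrings::readDNAStringSet(path)
    if (length(g) == 0L)
        stop("FASTA file contains no sequences: ", path)
    ## readDNAStringSet keeps the full header line; use the first word
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g)))
        stop("duplicate FASTA headers: ",
             paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
    if (any(Biostrings::width(g) == 0L))
        stop("empty sequence record in ", path)
    s <- toupper(as.character(g))
    nAmbig <- sum(vapply(s, function(x) {
        r <- charToRaw(x)
        sum(is.na(.BASE_LUT[as.integer(r)]) & r != charToRaw("N"))
    }, numeric(1)))
    if (nAmbig > 0) {
        message("loadFasta: converted ", nAmbig,
                " ambiguous base(s) to N")
        s <- vapply(s, function(x)
            gsub("[^ACGTN]", "N", x), character(1))
    }
    out <- Biostrings::DNAStringSet(s)
    names(out) <- names(g)
    out
}

#' Flag uniquely mappable positions by exact k-mer matching
#'
#' A position is flagged unique when the length-\code{k} sequence starting
#' there occurs exactly once in the genome, counting occurrences of both
#' the k-mer and its reverse complement as hits.  k-mers containing N are
#' never unique, and neither is a k-mer equal to its own reverse
#' complement (it hits its own site on both strands).  This is a
#' deterministic, aligner-free notion of mappability; aligner-derived
#' tracks can be brought in with \code{\link{importMappability}} instead.
#'
#' @param genome a \code{DNAStringSet}.
#' @param k read length in bp (default 50, the typical single-end NIPT
#'   read length); must be at most 64 and no longer than the longest
#'   chromosome.
#' @return a \code{\link{MappabilityTrack}}.
#' @export
computeUniquePositions <- function(genome, k = 50L) {
    k <- as.integer(k)
    if (k < 1L)
        stop("k must be >= 1")
    if (k > 64L)
        stop("exact k-mer uniqueness supports k <= 64")
    if (all(Biostrings::width(genome) < k))
        stop("k = ", k, " exceeds every chromosome length")
    seqs <- .seqStrings(genome)
    flags <- .kmerUniqueFlags(seqs, k)
    names(flags) <- names(seqs)
    new("MappabilityTrack", k = k, flags = flags,
        provenance = "computed")
}

#' Per-bin mappability fraction
#'
#' The mappability of a bin is the proportion of valid read start
#' positions inside it (positions whose k-mer fits in the chromosome) that
#' are uniquely mappable.
#'
#' @param track a \code{\link{MappabilityTrack}}.
#' @param scheme a bin scheme from \code{\link{binScheme}} (a
#'   \code{GRanges} of full-width bins).
#' @return numeric vector of mappability values in [0, 1], one per bin;
#'   bins with no valid start positions get 0.
#' @export
windowMappability <- function(track, scheme) {
    chroms <- as.character(seqnames(scheme))
    .checkChromsKnown(chroms, names(track@flags), "bin")
    out <- numeric(length(scheme))
    for (chrom in unique(chroms)) {
        f <- track@flags[[chrom]]
        npos <- length(f)          # valid starts: 1 .. L - k + 1
        L <- npos + track@k - 1L
        idx <- which(chroms == chrom)
        s <- start(scheme)[idx]
        e <- end(scheme)[idx]
        if (any(s < 1L | e > L))
            stop("bin outside chromosome ", chrom)
        p <- .prefix(f)
        hi <- pmin(e, npos)
        nvalid <- pmax(hi - s + 1L, 0L)
        uniq <- ifelse(nvalid > 0, p[hi + 1L] - p[s], 0)
        out[idx] <- ifelse(nvalid > 0, uniq / nvalid, 0)
    }
    out
}

#' Per-bin GC fraction
#'
#' GC is computed over A/C/G/T bases only; N bases are excluded from the
#' denominator.  Bins whose N fraction exceeds \code{nMax} are flagged
#' invalid via the \code{valid} attribute of the result.
#'
#' @param genome a \code{DNAStringSet}.
#' @param scheme bin scheme (\code{GRanges}).
#' @param nMax maximum tolerated N fraction per bin (default 0.1).
#' @return numeric vector of GC fractions (NaN when a bin is all N), with
#'   a logical attribute \code{"valid"}.
#' @export
windowGC <- function(genome, scheme, nMax = 0.1) {
    chroms <- as.character(seqnames(scheme))
    .checkChromsKnown(chroms, names(genome), "bin")
    cache <- .genomeCache(genome)
    gc <- numeric(length(scheme))
    valid <- logical(length(scheme))
    for (chrom in unique(chroms)) {
        cc <- .cacheCodes(cache, chrom)
        L <- length(cc$codes)
        idx <- which(chroms == chrom)
        s <- start(scheme)[idx]
        e <- end(scheme)[idx]
        if (any(s < 1L | e > L))
            stop("bin outside chromosome ", chrom)
        w <- e - s + 1L
        nN <- cc$n[e + 1L] - cc$n[s]
        nGC <- cc$gc[e + 1L] - cc$gc[s]
        gc[idx] <- nGC / (w - nN)
        valid[idx] <- (nN / w) <= nMax
    }
    attr(gc, "valid") <- valid
    gc
}

#' Load repeat annotation from a BED file
#'
#' Reads a BED3+ file of repeat intervals (0-based half-open, as in BED),
#' sorts and merges overlapping intervals per chromosome, and returns them
#' as a \code{GRanges} (1-based closed, the internal convention).
#'
#' @param path BED file path.
#' @return \code{GRanges} of merged repeat intervals.
#' @export
loadRepeatBed <- function(path) {
    if (!file.exists(path))
        stop("repeat BED not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
    if (!length(lines))
        stop("repeat BED has no intervals: ", path)
    fields <- strsplit(lines, "\t| +")
    bad <- which(vapply(fields, length, integer(1)) < 3L)
    if (length(bad))
        stop("malformed BED line ", bad[1], " in ", path)
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(s0) | is.na(e0) | s0 < 0 | e0 <= s0)
    if (length(bad))
        stop("invalid interval at BED line ", bad[1], " in ", path,
             " (need 0 <= start < end)")
    gr <- GRanges(chrom, IRanges(start = s0 + 1, end = e0))
    GenomicRanges::reduce(sort(gr))
}

#' Export / import a mappability track as bedGraph
#'
#' Windowed mappability values can be exchanged as bedGraph (chrom, start,
#' end, value in [0, 1]).  \code{importMappability} turns a base-pair
#' resolution bedGraph (value 1 = unique, 0 = not) back into a
#' \code{MappabilityTrack}; every position up to \code{length - k + 1} of
#' each listed chromosome must be covered.
#'
#' @param track a \code{MappabilityTrack}.
#' @param path output/input bedGraph path.
#' @param genome genome the imported track applies to.
#' @param k read length the imported track was computed at.
#' @return \code{exportMappability} returns the path invisibly;
#'   \code{importMappability} returns a \code{MappabilityTrack} with
#'   provenance \code{"imported"}.
#' @export
exportMappability <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(track@flags)) {
        f <- as.integer(track@flags[[chrom]])
        if (!length(f)) next
        r <- rle(f)
        e <- cumsum(r$lengths)
        s <- c(0L, e[-length(e)])
        writeLines(sprintf("%s\t%d\t%d\t%d", chrom, s, e, r$values), con)
    }
    invisible(path)
}

#' @rdname exportMappability
#' @export
importMappability <- function(path, genome, k = 50L) {
    k <- as.integer(k)
    gr <- rtracklayer::import(path, format = "bedGraph")
    .checkChromsKnown(seqnames(gr), names(genome), "mappability")
    lens <- .seqLengths(genome)
    flags <- lapply(names(genome), function(chrom) {
        npos <- max(lens[[chrom]] - k + 1L, 0L)
        v <- rep(NA, npos)
        sub <- gr[as.character(seqnames(gr)) == chrom]
        if (length(sub)) {
            s <- pmax(start(sub), 1L)
            e <- pmin(end(sub), npos)
            keep <- which(e >= s)
            for (i in keep)
                v[s[i]:e[i]] <- sub$score[i] >= 0.5
        }
        if (anyNA(v))
            stop("imported track does not cover chromosome ", chrom)
        v
    })
    names(flags) <- names(genome)
    new("MappabilityTrack", k = k, flags = flags,
        provenance = "imported")
}

#' Genome-wide unique fraction of a mappability track
#'
#' Fraction of valid read start positions flagged unique, pooled over all
#' chromosomes (i.e. weighted by the number of valid starts).
#'
#' @param track a \code{MappabilityTrack}.
#' @return a fraction in [0, 1].
#' @export
uniqueFraction <- function(track) {
    n <- sum(vapply(track@flags, length, integer(1)))
    if (n == 0L) return(NaN)
    sum(vapply(track@flags, sum, integer(1))) / n
}
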