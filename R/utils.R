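## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## byte -> 2-bit base code lookup (0=A,1=C,2=G,3=T, NA otherwise incl. N)
.BASE_LUT <- local({
    lut <- rep(NA_integer_, 256L)
    lut[utf8ToInt("A")] <- 0L
    lut[utf8ToInt("C")] <- 1L
    lut[utf8ToInt("G")] <- 2L
    lut[utf8ToInt("T")] <- 3L
    lut
})

## chromosome sequence (character scalar) -> integer base codes, NA for N
.baseCodes <- function(s) {
    .BASE_LUT[as.integer(charToRaw(s))]
}

## genome accessor: named character vector of sequences
.seqStrings <- function(genome) {
    s <- as.character(genome)
    names(s) <- names(genome)
    s
}

.seqLengths <- function(genome) {
    stats::setNames(Biostrings::width(genome), names(genome))
}

## prefix sums with a leading zero so sum over [i, j] = p[j + 1] - p[i]
.prefix <- function(x) c(0, cumsum(x))

## per-chromosome caches of base codes and GC / N prefix sums; recomputed
## lazily and attached to an environment keyed by chromosome name
.genomeCache <- function(genome) {
    env <- new.env(parent = emptyenv())
    env$strings <- .seqStrings(genome)
    env$codes <- new.env(parent = emptyenv())
    env
}

.cacheCodes <- function(cache, chrom) {
    if (is.null(cache$codes[[chrom]])) {
        codes <- .baseCodes(cache$strings[[chrom]])
        cache$codes[[chrom]] <- list(
            codes = codes,
            gc = .prefix(!is.na(codes) & (codes == 1L | codes == 2L)),
            n = .prefix(is.na(codes)))
    }
    cache$codes[[chrom]]
}

## group sums keeping empty groups; groups are 1-based indices <= ngroups
.groupSum <- function(values, groups, ngroups) {
    out <- numeric(ngroups)
    if (length(values)) {
        s <- rowsum(as.numeric(values), groups, reorder = FALSE)
        out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
}

## run code under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    code
}

.isChrY <- function(chrom) {
    tolower(as.character(chrom)) %in% c("chry", "y")
}

## 5' end, 1-based: leftmost base for + fragments, rightmost for -
.fivePrimeEnds <- function(frags) {
    str <- as.character(GenomicRanges::strand(frags))
    if (any(!str %in% c("+", "-")))
        stop("fragments must carry + or - strand")
    ifelse(str == "+", GenomicRanges::start(frags),
           GenomicRanges::end(frags))
}

#' Enumerate the 64 breakpoint 3-mers
#'
#' The breakpoint 3-mer of a fragment is the triplet of reference bases at
#' offsets -2, 0 and +1 relative to its 5' end (read-strand orientation),
#' written "X*YZ" with the wildcard at offset -1.  Motifs are ordered so
#' that the index of motif (b2, b0, b1) is 16*b2 + 4*b0 + b1 + 1 with
#' A,C,G,T coded 0..3.
#'
#' @return character vector of the 64 motif names.
#' @examples
#' length(breakpointMotifs())  # 64
#' @export
breakpointMotifs <- function() {
    g <- expand.grid(b1 = .BASES, b0 = .BASES, b2 = .BASES,
                     stringsAsFactors = FALSE)
    paste0(g$b2, "*", g$b0, g$b1)
}

## motif index (1..64, NA when context undefined) at 5' ends.
## For + strand fragments the context bases sit at pos-2, pos, pos+1 on the
## reference; for - strand fragments at pos+2, pos, pos-1, complemented.
.motifIndex <- function(codes, pos, minus) {
    L <- length(codes)
    if (!minus) {
        ok <- pos >= 3L & pos + 1L <= L
        b2 <- b0 <- b1 <- rep(NA_integer_, length(pos))
        b2[ok] <- codes[pos[ok] - 2L]
        b0[ok] <- codes[pos[ok]]
        b1[ok] <- codes[pos[ok] + 1L]
    } else {
        ok <- pos - 1L >= 1L & pos + 2L <= L
        b2 <- b0 <- b1 <- rep(NA_integer_, length(pos))
        b2[ok] <- 3L - codes[pos[ok] + 2L]
        b0[ok] <- 3L - codes[pos[ok]]
        b1[ok] <- 3L - codes[pos[ok] - 1L]
    }
    16L * b2 + 4L * b0 + b1 + 1L
}

## strand-oriented GC count of the length-l window anchored at the 5' end:
## [pos, pos+l-1] for +, [pos-l+1, pos] for -.  Returns NA when the window
## leaves the chromosome or contains N.
.windowGCCounts <- function(chromCache, pos, l, minus) {
    gcp <- chromCache$gc
    np <- chromCache$n
    L <- length(chromCache$codes)
    if (!minus) {
        ok <- pos + l - 1L <= L
        lo <- pos
    } else {
        ok <- pos - l + 1L >= 1L
        lo <- pos - l + 1L
    }
    out <- rep(NA_integer_, length(pos))
    idx <- which(ok)
    if (length(idx)) {
        loi <- lo[idx]
        hii <- loi + l
        hasN <- (np[hii] - np[loi]) > 0
        val <- as.integer(gcp[hii] - gcp[loi])
        val[hasN] <- NA_integer_
        out[idx] <- val
    }
    out
}

.checkChromsKnown <- function(chroms, known, what = "fragments") {
    bad <- setdiff(unique(as.character(chroms)), known)
    if (length(bad))
        stop(what, " reference chromosome(s) not in genome: ",
             paste(bad, collapse = ", "))
}
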