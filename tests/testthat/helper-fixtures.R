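## Fixture builders shared across tests; everything is generated in code.

toyGenome <- function(...) {
    seqs <- c(...)
    g <- Biostrings::DNAStringSet(unname(seqs))
    names(g) <- names(seqs)
    g
}

## random A/C/G/T genome without N, deterministic
randomGenome <- function(lens, seed = 1, gc = 0.45) {
    stopifnot(!is.null(names(lens)))
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    seqs <- vapply(lens, function(L) {
        p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
        paste(sample(c("A", "C", "G", "T"), L, TRUE, prob = p),
              collapse = "")
    }, character(1))
    toyGenome(seqs)
}

## GRanges fragment builder (1-based closed coordinates)
makeFragments <- function(chrom, start, end, strand = "+", mapq = 70L,
                          seqlengths = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand,
                                 seqlengths = seqlengths)
    S4Vectors::mcols(gr)$mapq <- as.integer(mapq)
    gr
}

## brute-force both-strand k-mer occurrence oracle
bruteForceUnique <- function(genome, k) {
    seqs <- as.character(genome)
    revcomp <- function(s)
        chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    kmers <- unlist(lapply(seqs, function(s) {
        L <- nchar(s)
        if (L < k) character(0) else substring(s, 1:(L - k + 1), k:L)
    }), use.names = FALSE)
    counts <- table(kmers)
    out <- lapply(seqs, function(s) {
        L <- nchar(s)
        if (L < k) return(logical(0))
        km <- substring(s, 1:(L - k + 1), k:L)
        vapply(km, function(x) {
            if (grepl("N", x)) return(FALSE)
            rc <- revcomp(x)
            n <- counts[x]
            n <- if (is.na(n)) 0 else unname(n)
            nrc <- counts[rc]
            nrc <- if (is.na(nrc)) 0 else unname(nrc)
            (n + nrc) == 1
        }, logical(1), USE.NAMES = FALSE)
    })
    names(out) <- names(genome)
    out
}

## MappabilityTrack where every position is unique (handy when the test
## is not about mappability)
allUniqueTrack <- function(genome, k = 25L) {
    lens <- Biostrings::width(genome)
    flags <- lapply(lens, function(L) rep(TRUE, max(L - k + 1L, 0L)))
    names(flags) <- names(genome)
    new("MappabilityTrack", k = as.integer(k), flags = flags,
        provenance = "computed")
}

writeTempFasta <- function(genome) {
    fa <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(genome, fa)
    fa
}
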