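#' Export result objects as TSV
#'
#' Writes the tabular content of a result object to a tab-separated file
#' with a header: GC strata tables (gc, n, fragments, rate, smooth), TV
#' score curves (window_length, tv_score), positional base profiles
#' (offset, A, C, G, T, n) and motif frequency tables (motif, plus,
#' minus, plus/minus proportions).
#'
#' @param x the object to export.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
setGeneric("exportTSV", function(x, path) standardGeneric("exportTSV"))

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname exportTSV
#' @export
setMethod("exportTSV", "GCStrataTable", function(x, path) {
    .writeTSV(x@strata, path)
})

#' @rdname exportTSV
#' @export
setMethod("exportTSV", "TVScoreCurve", function(x, path) {
    .writeTSV(data.frame(window_length = x@windowLengths,
                         tv_score = x@scores), path)
})

#' @rdname exportTSV
#' @export
setMethod("exportTSV", "PositionalBaseProfile", function(x, path) {
    .writeTSV(data.frame(offset = x@offsets, x@proportions,
                         n = x@counts, check.names = FALSE), path)
})

#' @rdname exportTSV
#' @export
setMethod("exportTSV", "MotifFrequencyTable", function(x, path) {
    tot <- pmax(colSums(x@counts), 1L)
    .writeTSV(data.frame(motif = rownames(x@counts),
                         plus = x@counts[, "plus"],
                         minus = x@counts[, "minus"],
                         plus_prop = x@counts[, "plus"] / tot[1],
                         minus_prop = x@counts[, "minus"] / tot[2]),
              path)
})
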