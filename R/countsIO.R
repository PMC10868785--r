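#' Write / read an sgRNA count matrix as TSV
#'
#' Plain-text exchange format: header row of sample ids with a leading
#' \code{guide_id} column, one row per guide, integer counts. The round trip
#' is lossless for the count matrix; sample QC lives in \code{colData} and is
#' not part of this file.
#'
#' @param counts A \linkS4class{ScreenCounts} or integer matrix with guide
#'   rownames.
#' @param path File path.
#' @param library Optional \linkS4class{GuideLibrary} used to attach guide
#'   annotation and enforce that rows are exactly the library's guides.
#' @return \code{readCountsTsv} returns a \linkS4class{ScreenCounts};
#'   \code{writeCountsTsv} returns \code{path} invisibly.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' p <- tempfile(fileext = ".tsv")
#' writeCountsTsv(m, p)
#' readCountsTsv(p)
#' @export
writeCountsTsv <- function(counts, path) {
    m <- if (is(counts, "ScreenCounts"))
        SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
    stopifnot(!is.null(rownames(m)))
    d <- data.frame(guide_id = rownames(m), m, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path, library = NULL) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA)
    if (colnames(d)[1] != "guide_id")
        stop("first column of ", path, " must be guide_id")
    ids <- as.character(d[[1]])
    m <- as.matrix(d[, -1, drop = FALSE])
    for (j in seq_len(ncol(m))) {
        v <- suppressWarnings(as.numeric(m[, j]))
        bad <- which(is.na(v) & !is.na(m[, j]))
        if (length(bad))
            stop("malformed count in ", path, " at row ", bad[1] + 1L,
                 " (guide ", ids[bad[1]], "), column '",
                 colnames(m)[j], "'")
        if (any(v < 0, na.rm = TRUE))
            stop("negative count in ", path, " at row ",
                 which(v < 0)[1] + 1L, ", column '", colnames(m)[j], "'")
        if (any(v != round(v), na.rm = TRUE))
            stop("non-integer count in ", path, ", column '",
                 colnames(m)[j], "'")
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    ScreenCounts(m, library = library)
}
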