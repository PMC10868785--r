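#' Synthesize amplicon reads from guide tallies
#'
#' Emits \code{depth} reads sampled from per-guide tallies (multinomially by
#' default, or by exact largest-remainder apportionment), each read being
#' \code{leftFlank + spacer + rightFlank} truncated or A-padded to the design
#' read length, with independent per-base substitution errors.
#'
#' @param tallies Named numeric vector of per-guide weights (e.g. sorted-cell
#'   tallies from \code{\link{tallyGuides}}); names must be library guide
#'   ids. All-zero tallies with positive depth are an error.
#' @param library A \linkS4class{GuideLibrary}.
#' @param design An \linkS4class{AmpliconDesign}.
#' @param depth Total number of reads.
#' @param errorRate Per-base substitution probability in [0, 1).
#' @param seed Integer seed.
#' @param exact If \code{TRUE}, read counts are apportioned proportionally
#'   (largest remainder) instead of multinomially sampled, so error-free
#'   extraction reproduces the tallies exactly.
#' @return A named \link[Biostrings]{DNAStringSet} of \code{depth} reads in
#'   shuffled order.
#' @examples
#' lib <- GuideLibrary(c("g1", "g2"), c("A", "B"), c("AAGGT", "CCCTA"))
#' des <- ampliconDesign("ACCG", "GTTT", 5L, readLength = 14L)
#' synthesizeReads(c(g1 = 2, g2 = 1), lib, des, depth = 3, exact = TRUE)
#' @export
synthesizeReads <- function(tallies, library, design, depth,
                            errorRate = 0, seed = 1L, exact = FALSE) {
    stopifnot(is(library, "GuideLibrary"), is(design, "AmpliconDesign"),
              depth >= 0, errorRate >= 0, errorRate < 1)
    if (depth == 0) return(Biostrings::DNAStringSet())
    bad <- setdiff(names(tallies), guideIds(library))
    if (length(bad))
        stop("tallies name guides absent from the library: ",
             paste(utils::head(bad, 5), collapse = ", "))
    if (sum(tallies) <= 0)
        stop("cannot synthesize ", depth, " reads from all-zero tallies")
    set.seed(seed)
    nz <- tallies[tallies > 0]
    counts <- if (exact) .apportion(nz, depth)
              else as.integer(stats::rmultinom(1, depth, nz))
    spc <- stats::setNames(library@guides$spacer, library@guides$guide_id)
    tmpl <- paste0(design@leftFlank, spc[names(nz)], design@rightFlank)
    tmpl <- substr(paste0(tmpl, strrep("A", design@readLength)),
                   1L, design@readLength)
    reads <- rep(tmpl, counts)
    reads <- reads[sample.int(length(reads))]
    x <- Biostrings::DNAStringSet(reads)
    if (errorRate > 0) x <- .injectErrors(x, errorRate)
    names(x) <- sprintf("read%07d", seq_along(x))
    x
}

## internal: independent per-base substitutions to a uniformly random
## different base
.injectErrors <- function(x, rate) {
    n <- length(x)
    L <- unique(Biostrings::width(x))
    stopifnot(length(L) == 1)
    at <- matrix(stats::runif(n * L) < rate, nrow = n)
    k <- sum(at)
    if (k == 0) return(x)
    ri <- row(at)[at]
    ci <- col(at)[at]
    o <- order(ri, ci)                 # per-read, left-to-right
    ri <- ri[o]; ci <- ci[o]
    cur <- substring(as.character(x)[ri], ci, ci)
    ## shift each hit base by 1-3 positions around the 4-letter alphabet
    sub <- .DNA_ALPHABET[((match(cur, .DNA_ALPHABET) - 1L +
                           sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
    letter <- vapply(split(sub, factor(ri, levels = seq_len(n))),
                     paste0, collapse = "", FUN.VALUE = "")
    Biostrings::replaceLetterAt(x, at, letter)
}

#' Write / read FASTQ
#'
#' Four-line FASTQ records via Biostrings; gzip compression inferred from a
#' \code{.gz} extension. Synthesized reads carry a constant quality string.
#'
#' @param reads A named \link[Biostrings]{DNAStringSet}.
#' @param path Output path (\code{.fastq} or \code{.fastq.gz}).
#' @param quality Single quality character replicated over each read.
#' @return \code{readFastq} returns a \link[Biostrings]{DNAStringSet};
#'   \code{writeFastq} returns \code{path} invisibly.
#' @export
writeFastq <- function(reads, path, quality = "I") {
    stopifnot(is(reads, "DNAStringSet"))
    if (is.null(names(reads)) && length(reads))
        names(reads) <- sprintf("read%07d", seq_along(reads))
    q <- Biostrings::BStringSet(strrep(quality, Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                compress = grepl("\\.gz$", path),
                                qualities = q)
    invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
    Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Extract spacers from reads
#'
#' Flank-anchored spacer extraction: finds the first exact occurrence of the
#' left flank and takes the following \code{spacerLength} bases; when the
#' design requires it, the bases after the spacer must equal the right flank.
#' This reproduces trimming the constant sequences that flank the 20 bp
#' spacer before matching to the library. Failures are data, not errors.
#'
#' @param reads Character vector or \link[Biostrings]{DNAStringSet}.
#' @param design An \linkS4class{AmpliconDesign}.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{spacer}
#'   (\code{NA} on failure) and \code{status}, one of \code{ok},
#'   \code{flank_not_found}, \code{truncated}, \code{right_flank_mismatch}.
#' @examples
#' des <- ampliconDesign("ACCG", "GTTT", 5L)
#' extractSpacers(c("ACCGAAGGTGTTT", "TTTTTTTTTTTTT"), des)
#' @export
extractSpacers <- function(reads, design) {
    stopifnot(is(design, "AmpliconDesign"))
    x <- as.character(reads)
    n <- length(x)
    nc <- nchar(x)
    pos <- regexpr(design@leftFlank, x, fixed = TRUE)
    start <- pos + nchar(design@leftFlank)
    end <- start + design@spacerLength - 1L
    status <- rep("ok", n)
    status[pos < 0] <- "flank_not_found"
    tr <- pos > 0 & end > nc
    status[tr] <- "truncated"
    if (design@requireRightFlank && nzchar(design@rightFlank)) {
        rfLen <- nchar(design@rightFlank)
        cand <- status == "ok"
        short <- cand & (end + rfLen > nc)
        status[short] <- "truncated"
        cand <- status == "ok"
        mism <- cand & substr(x, end + 1L, end + rfLen) != design@rightFlank
        status[mism] <- "right_flank_mismatch"
    }
    spacer <- rep(NA_character_, n)
    ok <- status == "ok"
    spacer[ok] <- substr(x[ok], start[ok], end[ok])
    DataFrame(spacer = spacer,
              status = factor(status, levels = c("ok", "flank_not_found",
                                                 "truncated",
                                                 "right_flank_mismatch")))
}

#' Count spacers against a library
#'
#' Extracts spacers and assigns them to library guides: exact hash matching
#' at \code{maxMismatch = 0}; at \code{maxMismatch = 1} a spacer matching
#' exactly one library spacer within Hamming distance 1 is assigned, while
#' spacers equidistant from several guides are counted ambiguous and
#' dropped (never split fractionally). The QC categories partition the
#' reads: \code{n_reads = n_assigned + n_flank_fail + n_no_match +
#' n_ambiguous}, where \code{n_flank_fail} counts every extraction failure.
#'
#' @param reads Character vector, \link[Biostrings]{DNAStringSet}, or a
#'   FASTQ path.
#' @param library A \linkS4class{GuideLibrary}.
#' @param design An \linkS4class{AmpliconDesign}.
#' @param maxMismatch 0 or 1.
#' @return List with \code{counts} (named integer over all library guides)
#'   and \code{qc} (named integer of the five QC categories).
#' @examples
#' lib <- GuideLibrary(c("g1", "g2"), c("A", "B"), c("AAGGT", "CCCTA"))
#' des <- ampliconDesign("ACCG", "GTTT", 5L, readLength = 14L)
#' rd <- synthesizeReads(c(g1 = 2, g2 = 1), lib, des, 3, exact = TRUE)
#' countSpacers(rd, lib, des)$counts
#' @export
countSpacers <- function(reads, library, design, maxMismatch = 0L) {
    stopifnot(is(library, "GuideLibrary"), is(design, "AmpliconDesign"),
              maxMismatch %in% c(0L, 1L))
    if (is.character(reads) && length(reads) == 1 && file.exists(reads))
        reads <- readFastq(reads)
    ex <- extractSpacers(reads, design)
    nReads <- nrow(ex)
    nFlankFail <- sum(ex$status != "ok")
    counts <- stats::setNames(integer(length(library)), guideIds(library))
    spacerOf <- stats::setNames(guideIds(library), library@guides$spacer)
    obs <- ex$spacer[ex$status == "ok"]
    nAssigned <- 0L; nAmbiguous <- 0L; nNoMatch <- 0L
    if (length(obs)) {
        tab <- table(obs)
        uq <- names(tab)
        hit <- spacerOf[uq]                      # NA when not exact
        exact <- !is.na(hit)
        add <- tapply(as.integer(tab[exact]), hit[exact], sum)
        counts[names(add)] <- counts[names(add)] + as.integer(add)
        nAssigned <- nAssigned + sum(tab[exact])
        rest <- uq[!exact]
        if (maxMismatch == 1L && length(rest)) {
            asg <- .hamming1Assign(rest, spacerOf)
            one <- !is.na(asg$guide) & !asg$ambiguous
            if (any(one)) {
                add <- tapply(as.integer(tab[rest[one]]), asg$guide[one], sum)
                counts[names(add)] <- counts[names(add)] + as.integer(add)
                nAssigned <- nAssigned + sum(tab[rest[one]])
            }
            nAmbiguous <- sum(tab[rest[asg$ambiguous]])
            nNoMatch <- sum(tab[rest[is.na(asg$guide) & !asg$ambiguous]])
        } else {
            nNoMatch <- sum(tab[!exact])
        }
    }
    list(counts = counts,
         qc = c(n_reads = nReads, n_assigned = as.integer(nAssigned),
                n_flank_fail = as.integer(nFlankFail),
                n_no_match = as.integer(nNoMatch),
                n_ambiguous = as.integer(nAmbiguous)))
}

## internal: assign each query spacer to the unique library spacer within
## Hamming distance 1, or flag ambiguity. Enumerates the 3L single-base
## neighbours of each query and looks them up in the spacer hash.
.hamming1Assign <- function(queries, spacerOf) {
    L <- unique(nchar(queries))
    stopifnot(length(L) == 1)
    guide <- rep(NA_character_, length(queries))
    ambiguous <- logical(length(queries))
    nbrGuides <- character(0)
    qIdx <- integer(0)
    for (p in seq_len(L)) {
        cur <- substr(queries, p, p)
        for (b in .DNA_ALPHABET) {
            sel <- cur != b
            if (!any(sel)) next
            v <- queries[sel]
            substr(v, p, p) <- b
            g <- spacerOf[v]
            hitsel <- !is.na(g)
            if (any(hitsel)) {
                nbrGuides <- c(nbrGuides, g[hitsel])
                qIdx <- c(qIdx, which(sel)[hitsel])
            }
        }
    }
    if (length(qIdx)) {
        byq <- split(nbrGuides, qIdx)
        for (nm in names(byq)) {
            i <- as.integer(nm)
            u <- unique(byq[[nm]])
            if (length(u) == 1L) guide[i] <- u else ambiguous[i] <- TRUE
        }
    }
    list(guide = guide, ambiguous = ambiguous)
}

#' Multinomial sequencing of sorted-pool tallies
#'
#' Shortcut sequencing model that skips read synthesis: samples \code{depth}
#' reads multinomially over the guide tallies and returns per-guide counts
#' directly. Statistically this is read synthesis at error rate 0 followed
#' by exact counting.
#'
#' @param tallies Named numeric vector over library guides.
#' @param depth Total read count.
#' @param seed Integer seed.
#' @return Named integer vector parallel to \code{tallies}.
#' @export
sequenceCounts <- function(tallies, depth, seed = 1L) {
    stopifnot(depth >= 0)
    if (sum(tallies) <= 0)
        stop("cannot sequence all-zero tallies")
    set.seed(seed)
    out <- stats::setNames(integer(length(tallies)), names(tallies))
    nz <- tallies > 0
    out[nz] <- as.integer(stats::rmultinom(1, depth, tallies[nz]))
    out
}
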