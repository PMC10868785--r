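## Shared fixtures and independent oracles, built in code at test time.

## independent naive O(n * window) local-Z oracle: explicit double loop with
## mean() / sd(), kept deliberately separate from the package's cumulative-sum
## implementation
naiveLocalZ <- function(lfc, meanAbundance, window, ids = NULL) {
    n <- length(lfc)
    ord <- if (is.null(ids)) order(meanAbundance)
           else order(meanAbundance, ids)
    y <- lfc[ord]
    half <- (window - 1L) %/% 2L
    z <- numeric(n)
    for (i in seq_len(n)) {
        s <- min(max(i - half, 1L), n - window + 1L)
        w <- y[s:(s + window - 1L)]
        m <- mean(w)
        sdv <- stats::sd(w)
        z[i] <- if (sdv <= 1e-12 * (1 + abs(m))) 0 else (y[i] - m) / sdv
    }
    out <- numeric(n)
    out[ord] <- z
    out
}

## PulseData built directly from vectors
makePulseData <- function(area, height = area, width = rep(1, length(area)),
                          aggregated = rep(FALSE, length(area))) {
    new("PulseData", pulses = S4Vectors::DataFrame(
        cell_id = seq_along(area), height = height, width = width,
        area = area, truth_aggregated = aggregated))
}

## tiny 2-guide library + short-read design used by the counting fixtures
tinyDesign <- function() ampliconDesign(leftFlank = "ACCG",
                                        rightFlank = "GTTT",
                                        spacerLength = 5L, readLength = 14L)

tinyLibrary <- function() GuideLibrary(c("g1", "g2"), c("GENEA", "GENEB"),
                                       c("AAGGT", "CCCTA"))

## counts matrix for a screen where one gene's guides are enriched `fold`-x
## in the aggregate-positive pool; everything else is flat
plantedCounts <- function(library, gene, fold, baseCount = 500L,
                          nReplicates = 2L, seed = 1L) {
    set.seed(seed)
    ids <- guideIds(library)
    m <- matrix(0L, nrow = length(ids), ncol = 2L * nReplicates,
                dimnames = list(ids, as.vector(outer(
                    c("pos", "neg"), seq_len(nReplicates),
                    function(a, b) sprintf("%s_rep%d", a, b)))))
    boost <- ifelse(guideGenes(library) == gene, fold, 1)
    for (r in seq_len(nReplicates)) {
        m[, sprintf("pos_rep%d", r)] <-
            stats::rpois(length(ids), baseCount * boost)
        m[, sprintf("neg_rep%d", r)] <- stats::rpois(length(ids), baseCount)
    }
    cd <- S4Vectors::DataFrame(
        condition = rep(c("pos", "neg"), nReplicates),
        replicate = rep(seq_len(nReplicates), each = 2)[
            order(rep(seq_len(nReplicates), 2))],
        row.names = colnames(m))
    cd$condition <- sub("_rep\\d+$", "", rownames(cd))
    cd$replicate <- as.integer(sub("^.*_rep", "", rownames(cd)))
    ScreenCounts(m, library, cd)
}

## md5 of every regular file in a directory, named by relative path
dirChecksums <- function(dir) {
    f <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    s <- tools::md5sum(f)
    names(s) <- sub(paste0("^", dir, "/?"), "", f)
    s
}
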