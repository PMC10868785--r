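#' Depth-normalize sgRNA counts
#'
#' Per sample: divide each count by the sample mean count, multiply by the
#' scale (one million) and add the pseudocount, i.e.
#' \code{out = counts / mean(counts) * scale + pseudocount}. The pseudocount
#' is added after scaling, so downstream ratios use (scaled + 1) values.
#' Multiplying a sample by any positive constant leaves its normalized
#' vector unchanged.
#'
#' @param counts Non-negative numeric vector (one sample) or matrix (one
#'   column per sample).
#' @param config A \linkS4class{ScoringConfig}.
#' @return Normalized vector or matrix of the same shape.
#' @examples
#' normalizeCounts(c(10, 20, 30))  # 500001, 1000001, 1500001
#' @export
normalizeCounts <- function(counts, config = scoringConfig()) {
    if (is.matrix(counts))
        return(apply(counts, 2, normalizeCounts, config = config))
    if (any(counts < 0)) stop("counts must be non-negative")
    m <- mean(counts)
    if (m == 0) stop("all-zero sample cannot be normalized")
    counts / m * config@scale + config@pseudocount
}

#' Per-guide log fold change between sorted pools
#'
#' \code{lfc_i = log(norm_pos_i / norm_neg_i, logBase)}: the log-ratio of a
#' guide's normalized abundance in the aggregate-positive pool over the
#' aggregate-negative pool (base 2 by default, matching an LFC hit
#' threshold of 1).
#'
#' @param normPos,normNeg Normalized abundance vectors aligned to the same
#'   guide order.
#' @param config A \linkS4class{ScoringConfig}.
#' @return Numeric LFC vector.
#' @examples
#' guideLfc(2000002, 1000001)  # exactly 1
#' @export
guideLfc <- function(normPos, normNeg, config = scoringConfig()) {
    if (length(normPos) != length(normNeg))
        stop("normPos and normNeg must have the same length")
    log(normPos / normNeg, base = config@logBase)
}

#' Local Z-scores over the abundance ranking
#'
#' Corrects the abundance dependence of fold-change variance: guides are
#' ranked by mean abundance between the two pools (ties broken by guide id),
#' and each guide's LFC is standardized against the mean and sample SD of
#' the LFCs in a window of exactly \code{window} guides centred on it
#' (shifted inward at the edges so the window never shrinks; the focal guide
#' is included unless \code{excludeFocal}). A window with zero SD yields
#' z = 0.
#'
#' @param lfc Numeric LFC vector.
#' @param meanAbundance Ranking key, typically \code{(normPos + normNeg)/2}.
#' @param window Window size in guides (clamped to n with a warning when
#'   larger).
#' @param guideIds Optional ids used to break ranking ties deterministically.
#' @param excludeFocal Exclude the focal guide from its own window
#'   statistics.
#' @return Numeric z vector parallel to the input order.
#' @examples
#' localZ(c(0, 0, 0, 4), c(1, 2, 3, 4), window = 4)
#' @export
localZ <- function(lfc, meanAbundance, window = 2000L, guideIds = NULL,
                   excludeFocal = FALSE) {
    n <- length(lfc)
    if (n < 2) stop("need at least 2 guides for local Z")
    stopifnot(length(meanAbundance) == n)
    window <- as.integer(window)
    if (window > n) {
        warning("window ", window, " exceeds ", n, " guides; using ", n)
        window <- n
    }
    if (window < 2) stop("window must be >= 2")
    ord <- if (is.null(guideIds)) order(meanAbundance)
           else order(meanAbundance, guideIds)
    y <- lfc[ord]
    c0 <- mean(y)                      # centring improves cumsum accuracy
    yc <- y - c0
    S <- c(0, cumsum(yc))
    Q <- c(0, cumsum(yc^2))
    half <- (window - 1L) %/% 2L
    start <- pmin(pmax(seq_len(n) - half, 1L), n - window + 1L)
    end <- start + window - 1L
    sw <- S[end + 1L] - S[start]
    qw <- Q[end + 1L] - Q[start]
    if (excludeFocal) {
        m <- (sw - yc) / (window - 1L)
        v <- (qw - yc^2 - (window - 1L) * m^2) / (window - 2L)
    } else {
        m <- sw / window
        v <- (qw - window * m^2) / (window - 1L)
    }
    sdw <- sqrt(pmax(v, 0))
    z <- ifelse(sdw <= 1e-12 * (1 + abs(m)), 0, (yc - m) / sdw)
    out <- numeric(n)
    out[ord] <- z
    out
}

#' Gene phenotype from the two strongest guides
#'
#' For each gene, takes the two guides with the largest absolute local Z
#' (ties broken by guide order) and returns the mean of their signed z.
#' Single-guide genes return that z and are flagged by \code{n_guides = 1}.
#'
#' @param z Numeric local Z vector.
#' @param genes Character vector of gene labels parallel to \code{z}.
#' @return A data.frame with columns \code{gene}, \code{n_guides},
#'   \code{phenotype}, \code{mean_z}, in first-appearance gene order.
#' @examples
#' genePhenotype(c(0.1, -3.0, 2.5, 0.2), rep("G", 4))$phenotype  # -0.25
#' @export
genePhenotype <- function(z, genes) {
    stopifnot(length(z) == length(genes), length(z) > 0)
    idx <- split(seq_along(z), factor(genes, levels = unique(genes)))
    res <- vapply(idx, function(i) {
        zi <- z[i]
        top <- i[order(-abs(zi), seq_along(zi))][seq_len(min(2L, length(zi)))]
        c(length(i), mean(z[top]), mean(zi))
    }, numeric(3))
    data.frame(gene = names(idx), n_guides = as.integer(res[1, ]),
               phenotype = res[2, ], mean_z = res[3, ],
               row.names = NULL)
}

#' Permutation p-values for gene mean local Z
#'
#' The observed statistic of a gene is the mean local Z over all its guides.
#' Its significance is the two-sided empirical tail probability against a
#' null distribution of means of equally many z-values drawn without
#' replacement from the permutation pool — equivalent to permuting
#' guide-to-gene assignments. One null is built per distinct gene size and
#' shared across genes of that size. Sampled p-values use add-one smoothing,
#' \code{p = (1 + #(|null| >= |obs|)) / (nPerm + 1)}, so the smallest
#' attainable value is \code{1/(nPerm + 1)}. When the number of distinct
#' subsets \code{choose(N, s)} is at most \code{exhaustiveCap}, all subsets
#' are enumerated and the exact tail fraction is returned instead.
#'
#' @param z Numeric z vector of the genes' guides.
#' @param genes Gene labels parallel to \code{z}.
#' @param pool Numeric permutation pool (defaults to \code{z} itself;
#'   normally all targeting-guide z-values).
#' @param config A \linkS4class{ScoringConfig}; \code{nPerm},
#'   \code{exhaustiveCap} and \code{seed} are used.
#' @return Named numeric vector of p-values, one per distinct gene.
#' @examples
#' ## pool (1,2,3), gene owns z = 2 and 3: exact two-sided p = 1/3
#' genePvalue(c(2, 3), c("G", "G"), pool = c(1, 2, 3))
#' @export
genePvalue <- function(z, genes, pool = z, config = scoringConfig()) {
    stopifnot(length(z) == length(genes), length(pool) > 0)
    idx <- split(seq_along(z), factor(genes, levels = unique(genes)))
    obs <- vapply(idx, function(i) mean(z[i]), numeric(1))
    sizes <- lengths(idx)
    if (any(sizes > length(pool)))
        stop("gene size exceeds permutation pool size")
    set.seed(stageSeed(config@seed, "pvalue"))
    p <- stats::setNames(numeric(length(obs)), names(obs))
    for (s in sort(unique(sizes))) {
        sel <- sizes == s
        nSub <- suppressWarnings(choose(length(pool), s))
        if (is.finite(nSub) && nSub <= config@exhaustiveCap) {
            null <- if (s == length(pool)) mean(pool)
                    else colMeans(utils::combn(pool, s))
            nullAbs <- sort(abs(null))
            ge <- length(null) -
                findInterval(abs(obs[sel]) - 1e-12, nullAbs)
            p[sel] <- ge / length(null)
        } else {
            null <- perm_null_means(pool, s, config@nPerm)
            nullAbs <- sort(abs(null))
            ge <- config@nPerm -
                findInterval(abs(obs[sel]) - 1e-12, nullAbs)
            p[sel] <- (1 + ge) / (config@nPerm + 1)
        }
    }
    p
}

#' Average guide statistics across replicates
#'
#' Combines per-replicate guide statistics by the unweighted mean of LFC,
#' local Z, mean abundance and normalized abundances; a single replicate
#' passes through unchanged. Replicates must cover identical guide sets.
#'
#' @param statsList List of per-replicate data.frames (or DataFrames) with
#'   columns \code{guide_id}, \code{gene}, \code{norm_pos}, \code{norm_neg},
#'   \code{mean_abundance}, \code{lfc}, \code{local_z}.
#' @return A \link[S4Vectors]{DataFrame} of combined statistics in the first
#'   replicate's guide order.
#' @export
aggregateReplicates <- function(statsList) {
    stopifnot(length(statsList) >= 1)
    ref <- statsList[[1]]
    if (length(statsList) == 1) return(DataFrame(ref))
    for (k in seq_along(statsList)[-1]) {
        dk <- statsList[[k]]
        if (!setequal(dk$guide_id, ref$guide_id)) {
            miss <- c(setdiff(ref$guide_id, dk$guide_id),
                      setdiff(dk$guide_id, ref$guide_id))
            stop("replicate ", k, " guide set differs; e.g. ",
                 paste(utils::head(miss, 5), collapse = ", "))
        }
    }
    num <- c("norm_pos", "norm_neg", "mean_abundance", "lfc", "local_z")
    acc <- as.data.frame(ref)[, num]
    for (k in seq_along(statsList)[-1]) {
        dk <- as.data.frame(statsList[[k]])
        dk <- dk[match(ref$guide_id, dk$guide_id), ]
        acc <- acc + dk[, num]
    }
    acc <- acc / length(statsList)
    out <- DataFrame(guide_id = ref$guide_id, gene = ref$gene, acc)
    out
}

#' Call screen hits
#'
#' A gene is a hit when its p-value is below the p threshold and its
#' absolute phenotype exceeds the phenotype threshold (p < 0.005 and
#' |phenotype| > 1 by default); the sign of the phenotype gives the hit
#' direction, separating more-aggregation from less-aggregation hits.
#'
#' @param results data.frame or DataFrame with \code{p_value} and
#'   \code{phenotype} columns.
#' @param config A \linkS4class{ScoringConfig}.
#' @return The input with logical \code{is_hit} and integer \code{direction}
#'   (sign of phenotype) columns set.
#' @export
callHits <- function(results, config = scoringConfig()) {
    results$is_hit <- results$p_value < config@pThreshold &
        abs(results$phenotype) > config@phenotypeThreshold
    results$direction <- as.integer(sign(results$phenotype))
    results
}

#' Score NTC pseudo-genes
#'
#' Partitions the non-targeting-control guides into consecutive groups of
#' \code{ntcPseudoSize} (remainder dropped) and scores each group exactly
#' like a gene — phenotype from the two strongest guides and a permutation
#' p-value against the same pool. With 1000 NTC guides and groups of 4 this
#' yields 250 pseudo-genes whose p-values should be uniform in a null
#' screen, anchoring the calibration of the test.
#'
#' @param z Numeric local Z of the NTC guides, in library order.
#' @param pool Permutation pool (normally the targeting-guide z-values).
#' @param config A \linkS4class{ScoringConfig}.
#' @return A \link[S4Vectors]{DataFrame} of pseudo-gene results with the
#'   same columns as gene results.
#' @export
ntcPseudogenes <- function(z, pool, config = scoringConfig()) {
    s <- config@ntcPseudoSize
    if (length(z) < s)
        stop("need at least ", s, " NTC guides to form a pseudo-gene")
    k <- length(z) %/% s
    z <- z[seq_len(k * s)]
    grp <- sprintf("NTC_pseudo_%04d", rep(seq_len(k), each = s))
    ph <- genePhenotype(z, grp)
    ph$p_value <- unname(genePvalue(z, grp, pool = pool, config = config))
    DataFrame(callHits(ph, config))
}

#' Score a pulse-shape CRISPR screen
#'
#' Full composition of the scoring algorithm on an sgRNA count matrix with
#' aggregate-positive / aggregate-negative sample pairs per replicate:
#' per-sample depth normalization, per-guide log fold change, local Z over
#' the abundance ranking (per replicate), unweighted-mean replicate
#' aggregation, gene phenotype from the two strongest guides, permutation
#' p-values over all guides, hit calling, and NTC pseudo-gene calibration.
#' Deterministic for a fixed \code{config@seed}.
#'
#' @param counts A \linkS4class{ScreenCounts} whose \code{colData} has
#'   \code{condition} (\code{"pos"} / \code{"neg"}) and \code{replicate}
#'   columns, or an integer matrix plus explicit \code{samplePairs}.
#' @param library A \linkS4class{GuideLibrary} covering exactly the count
#'   rows.
#' @param config A \linkS4class{ScoringConfig}.
#' @param samplePairs Optional data.frame with columns \code{pos},
#'   \code{neg} naming the paired columns of each replicate (overrides
#'   \code{colData}).
#' @return A \linkS4class{ScreenScores}.
#' @examples
#' lib <- generateLibrary(20, 4, 20, spacerLength = 6, seed = 1)
#' m <- matrix(rpois(100 * 2, 100), ncol = 2,
#'             dimnames = list(guideIds(lib), c("pos_r1", "neg_r1")))
#' sc <- ScreenCounts(m, lib, S4Vectors::DataFrame(
#'     condition = c("pos", "neg"), replicate = c(1, 1),
#'     row.names = colnames(m)))
#' scoreScreen(sc, lib, scoringConfig(window = 40L, nPerm = 100L))
#' @export
scoreScreen <- function(counts, library, config = scoringConfig(),
                        samplePairs = NULL) {
    stopifnot(is(library, "GuideLibrary"))
    if (is(counts, "ScreenCounts")) {
        m <- SummarizedExperiment::assay(counts, "counts")
        if (is.null(samplePairs)) {
            cd <- SummarizedExperiment::colData(counts)
            if (!all(c("condition", "replicate") %in% colnames(cd)))
                stop("colData needs 'condition' and 'replicate' columns ",
                     "(or pass samplePairs)")
            reps <- unique(cd$replicate)
            samplePairs <- do.call(rbind, lapply(reps, function(r) {
                pos <- rownames(cd)[cd$replicate == r & cd$condition == "pos"]
                neg <- rownames(cd)[cd$replicate == r & cd$condition == "neg"]
                if (length(pos) != 1 || length(neg) != 1)
                    stop("replicate ", r, " must have exactly one pos and ",
                         "one neg sample")
                data.frame(pos = pos, neg = neg)
            }))
        }
    } else {
        m <- as.matrix(counts)
        if (is.null(samplePairs))
            stop("samplePairs is required for a bare matrix")
    }
    if (!setequal(rownames(m), guideIds(library)))
        stop("count rows and library guides differ")
    m <- m[guideIds(library), , drop = FALSE]
    genes <- guideGenes(library)
    ids <- guideIds(library)
    ntc <- isNTC(library)

    perRep <- lapply(seq_len(nrow(samplePairs)), function(k) {
        npos <- normalizeCounts(m[, samplePairs$pos[k]], config)
        nneg <- normalizeCounts(m[, samplePairs$neg[k]], config)
        ab <- (npos + nneg) / 2
        lfc <- guideLfc(npos, nneg, config)
        z <- .replicateLocalZ(lfc, ab, ids, ntc, config)
        DataFrame(guide_id = ids, gene = genes, norm_pos = unname(npos),
                  norm_neg = unname(nneg), mean_abundance = unname(ab),
                  lfc = unname(lfc), local_z = z)
    })
    gs <- aggregateReplicates(perRep)

    tz <- gs$local_z[!ntc]
    tgenes <- gs$gene[!ntc]
    pool <- if (config@includeNtcInNull) gs$local_z else tz
    res <- genePhenotype(tz, tgenes)
    res$p_value <- unname(genePvalue(tz, tgenes, pool = pool,
                                     config = config))
    res <- callHits(res, config)
    res <- res[order(res$p_value, -abs(res$phenotype), res$gene), ]
    rownames(res) <- NULL

    ntcRes <- if (sum(ntc) >= config@ntcPseudoSize)
        ntcPseudogenes(gs$local_z[ntc], pool = pool, config = config)
    else DataFrame()
    new("ScreenScores", geneResults = DataFrame(res),
        guideStats = gs, ntcResults = ntcRes, config = config)
}

## internal: local Z for one replicate honouring the NTC window flag
.replicateLocalZ <- function(lfc, ab, ids, ntc, config) {
    if (config@includeNtcInWindow || !any(ntc) || all(ntc)) {
        localZ(lfc, ab, config@window, guideIds = ids,
               excludeFocal = config@excludeFocal)
    } else {
        z <- numeric(length(lfc))
        z[!ntc] <- localZ(lfc[!ntc], ab[!ntc], config@window,
                          guideIds = ids[!ntc],
                          excludeFocal = config@excludeFocal)
        z[ntc] <- localZ(lfc[ntc], ab[ntc],
                         min(config@window, sum(ntc)),
                         guideIds = ids[ntc],
                         excludeFocal = config@excludeFocal)
        z
    }
}

#' Write scoring result tables
#'
#' \code{gene_results.tsv} (gene, n_guides, phenotype, mean_z, p_value,
#' is_hit, direction; sorted by p-value, then decreasing |phenotype|, then
#' gene), \code{guide_stats.tsv} and \code{ntc_pseudogenes.tsv}.
#'
#' @param scores A \linkS4class{ScreenScores}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
writeScreenScores <- function(scores, dir) {
    stopifnot(is(scores, "ScreenScores"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("gene_results.tsv", "guide_stats.tsv",
                              "ntc_pseudogenes.tsv"))
    utils::write.table(as.data.frame(scores@geneResults), paths[1],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(scores@guideStats), paths[2],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(scores@ntcResults), paths[3],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
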