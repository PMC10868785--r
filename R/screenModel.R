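#' Generate a synthetic sgRNA library
#'
#' Builds a Brunello-like pooled library: \code{nGenes * guidesPerGene}
#' targeting guides plus \code{nNtc} non-targeting controls, each with a
#' unique random spacer of fixed length. Deterministic for a fixed seed.
#'
#' @param nGenes Number of targeting genes.
#' @param guidesPerGene Guides per gene (Brunello averages 4).
#' @param nNtc Number of non-targeting control guides (Brunello has 1000).
#' @param spacerLength Spacer length in nt (default 20).
#' @param seed Integer seed.
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' lib <- generateLibrary(nGenes = 3, guidesPerGene = 4, nNtc = 2, seed = 1)
#' length(lib)
#' @export
generateLibrary <- function(nGenes, guidesPerGene = 4L, nNtc = 1000L,
                            spacerLength = 20L, seed = 1L) {
    stopifnot(nGenes >= 0, guidesPerGene >= 0, nNtc >= 0, spacerLength >= 1)
    total <- nGenes * guidesPerGene + nNtc
    ## 4^L >= total, compared in log space to dodge overflow at L = 20
    if (spacerLength * log(4) < log(max(total, 1)))
        stop("spacer space 4^", spacerLength,
             " is too small to guarantee ", total, " unique spacers")
    set.seed(seed)
    spacer <- .randomSpacers(total, spacerLength)
    gene <- c(rep(sprintf("GENE%05d", seq_len(nGenes)), each = guidesPerGene),
              rep(NTC_SENTINEL, nNtc))
    guide_id <- c(
        if (nGenes > 0 && guidesPerGene > 0)
            paste0(rep(sprintf("GENE%05d", seq_len(nGenes)),
                       each = guidesPerGene),
                   "_g", rep(seq_len(guidesPerGene), nGenes))
        else character(),
        if (nNtc > 0) sprintf("NTC_%05d", seq_len(nNtc)) else character())
    GuideLibrary(guide_id, gene, spacer)
}

## internal: n unique random spacers of length L
.randomSpacers <- function(n, L) {
    if (n == 0) return(character())
    draw <- function(k) {
        m <- matrix(sample(.DNA_ALPHABET, k * L, replace = TRUE), nrow = k)
        do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    s <- draw(n)
    while (anyDuplicated(s)) {                       # collisions are rare
        dup <- which(duplicated(s))
        s[dup] <- draw(length(dup))
    }
    s
}

#' Plant gene effects and guide efficacies
#'
#' Selects \code{nUp} genes as positive regulators of inclusion formation
#' (knockout increases the log-odds of aggregation) and \code{nDown} as
#' negative regulators; all other genes and the NTC sentinel get effect
#' exactly 0. Every guide receives a knockout efficacy.
#'
#' @param library A \linkS4class{GuideLibrary}.
#' @param nUp,nDown Numbers of positive / negative regulators to plant.
#' @param magnitudeSampler Function \code{n -> n} positive effect magnitudes
#'   on the log-odds scale.
#' @param efficacySampler Function \code{n -> n} efficacies in [0, 1].
#' @param baseLogit Baseline log-odds of inclusion in an unperturbed cell.
#' @param seed Integer seed.
#' @return A \linkS4class{ScreenTruth}.
#' @examples
#' lib <- generateLibrary(10, 4, 5, seed = 1)
#' truth <- assignEffects(lib, nUp = 2, nDown = 1, seed = 1)
#' table(sign(geneEffects(truth)))
#' @export
assignEffects <- function(library, nUp = 0L, nDown = 0L,
                          magnitudeSampler = function(n) stats::runif(n, 1, 3),
                          efficacySampler = function(n) stats::rbeta(n, 8, 2),
                          baseLogit = stats::qlogis(0.1), seed = 1L) {
    stopifnot(is(library, "GuideLibrary"), nUp >= 0, nDown >= 0)
    genes <- targetGenes(library)
    if (nUp + nDown > length(genes))
        stop("requested ", nUp + nDown, " regulators but the library has ",
             length(genes), " targeting genes")
    set.seed(seed)
    effect <- stats::setNames(numeric(length(genes)), genes)
    if (nUp + nDown > 0) {
        chosen <- sample(genes, nUp + nDown)
        mags <- abs(magnitudeSampler(nUp + nDown))
        if (nUp > 0) effect[chosen[seq_len(nUp)]] <- mags[seq_len(nUp)]
        if (nDown > 0) effect[chosen[nUp + seq_len(nDown)]] <-
            -mags[nUp + seq_len(nDown)]
    }
    effect[NTC_SENTINEL] <- 0
    eff <- pmin(pmax(efficacySampler(length(library)), 0), 1)
    names(eff) <- guideIds(library)
    new("ScreenTruth", library = library, geneEffect = effect,
        guideEfficacy = eff, baseLogit = baseLogit)
}

#' Simulate a single-guide cell population
#'
#' Each cell draws one guide (per-guide abundances log-normally dispersed to
#' emulate library skew), its knockout succeeds with the guide's efficacy,
#' and it forms an inclusion with probability
#' \code{plogis(baseLogit + effect * ko_success)}. Reporter expression is
#' log-normal; aggregated cells draw the fraction of fluorescence
#' concentrated in the inclusion from a scaled Beta distribution.
#'
#' @param truth A \linkS4class{ScreenTruth}.
#' @param nCells Number of cells (coverage x number of guides in a real
#'   screen; the screen used more than 1000x coverage).
#' @param guideAbundanceSpread Log-normal sigma of per-guide abundance
#'   (0 = perfectly even library).
#' @param expressionSpread Log-normal sigma of reporter expression.
#' @param meanFluorescence Median reporter fluorescence (arbitrary units).
#' @param punctateShape Beta shape parameters of the punctate-fraction
#'   sampler for aggregated cells.
#' @param punctateRange Interval the Beta draw is scaled into.
#' @param seed Integer seed.
#' @return A \linkS4class{CellPopulation}.
#' @examples
#' lib <- generateLibrary(5, 4, 5, seed = 1)
#' truth <- assignEffects(lib, seed = 1)
#' pop <- simulatePopulation(truth, nCells = 1000, seed = 1)
#' mean(cells(pop)$aggregated)
#' @export
simulatePopulation <- function(truth, nCells,
                               guideAbundanceSpread = 0.5,
                               expressionSpread = 0.5,
                               meanFluorescence = 1000,
                               punctateShape = c(5, 2),
                               punctateRange = c(0.3, 0.95),
                               seed = 1L) {
    stopifnot(is(truth, "ScreenTruth"), nCells >= 1,
              guideAbundanceSpread >= 0, expressionSpread >= 0,
              meanFluorescence > 0)
    lib <- truth@library
    nG <- length(lib)
    if (nG == 0) stop("library has no guides")
    set.seed(seed)
    w <- if (guideAbundanceSpread > 0)
        stats::rlnorm(nG, 0, guideAbundanceSpread) else rep(1, nG)
    gidx <- sample.int(nG, nCells, replace = TRUE, prob = w)
    gid <- guideIds(lib)[gidx]
    eff <- truth@guideEfficacy[gid]
    ko <- stats::runif(nCells) < eff
    e <- truth@geneEffect[guideGenes(lib)[gidx]]
    p_agg <- stats::plogis(truth@baseLogit + e * ko)
    aggregated <- stats::runif(nCells) < p_agg
    fl <- stats::rlnorm(nCells, log(meanFluorescence), expressionSpread)
    pf <- numeric(nCells)
    nA <- sum(aggregated)
    if (nA > 0)
        pf[aggregated] <- punctateRange[1] + diff(punctateRange) *
            stats::rbeta(nA, punctateShape[1], punctateShape[2])
    new("CellPopulation",
        cells = DataFrame(cell_id = seq_len(nCells), guide_id = gid,
                          ko_success = unname(ko),
                          total_fluorescence = unname(fl),
                          aggregated = unname(aggregated),
                          punctate_fraction = pf),
        library = lib)
}

#' Tally cells per guide
#'
#' Counts how many cells of a population (or sorted subset of one) carry
#' each library guide; guides with no cells report 0.
#'
#' @param x A \linkS4class{CellPopulation}, or a \link[S4Vectors]{DataFrame}
#'   of cells with a \code{guide_id} column.
#' @param library The \linkS4class{GuideLibrary} (taken from \code{x} when it
#'   is a population).
#' @return Named integer vector over all library guides.
#' @export
tallyGuides <- function(x, library = NULL) {
    if (is(x, "CellPopulation")) {
        library <- x@library
        gid <- x@cells$guide_id
    } else {
        stopifnot(!is.null(library), "guide_id" %in% colnames(x))
        gid <- x$guide_id
    }
    tab <- table(factor(gid, levels = guideIds(library)))
    stats::setNames(as.integer(tab), guideIds(library))
}

## ------------------------------------------------------------------ library IO

#' Read / write a guide library
#'
#' Plain-text exchange format with header \code{guide_id,gene,spacer};
#' comma- or tab-separated depending on the file extension (.csv vs
#' .tsv/.txt). NTC guides carry the literal \code{NTC} in the gene column.
#'
#' @param library A \linkS4class{GuideLibrary}.
#' @param path File path.
#' @return \code{readGuideLibrary} returns a \linkS4class{GuideLibrary};
#'   \code{writeGuideLibrary} returns \code{path} invisibly.
#' @export
writeGuideLibrary <- function(library, path) {
    stopifnot(is(library, "GuideLibrary"))
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    utils::write.table(as.data.frame(library@guides), path, sep = sep,
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGuideLibrary
#' @export
readGuideLibrary <- function(path) {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character")
    need <- c("guide_id", "gene", "spacer")
    if (!all(need %in% colnames(d)))
        stop("library file must have columns ", paste(need, collapse = ", "))
    GuideLibrary(d$guide_id, d$gene, d$spacer)
}

#' Export a cell population to TSV
#'
#' One row per cell; intended for debugging and inspection.
#'
#' @param population A \linkS4class{CellPopulation}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCellPopulation <- function(population, path) {
    stopifnot(is(population, "CellPopulation"))
    utils::write.table(as.data.frame(population@cells), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the planted truth tables
#'
#' Two TSVs: per-gene effects (\code{<stem>_genes.tsv}) and per-guide
#' efficacies (\code{<stem>_guides.tsv}).
#'
#' @param truth A \linkS4class{ScreenTruth}.
#' @param stem Path stem, e.g. \code{"out/truth"}.
#' @return Character vector of the two paths, invisibly.
#' @export
writeScreenTruth <- function(truth, stem) {
    stopifnot(is(truth, "ScreenTruth"))
    pg <- paste0(stem, "_genes.tsv")
    pu <- paste0(stem, "_guides.tsv")
    utils::write.table(
        data.frame(gene = names(truth@geneEffect),
                   effect_logit = unname(truth@geneEffect),
                   base_logit = truth@baseLogit),
        pg, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(guide_id = names(truth@guideEfficacy),
                   efficacy = unname(truth@guideEfficacy)),
        pu, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(pg, pu))
}
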