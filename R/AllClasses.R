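#' Sentinel gene label for non-targeting control guides
#'
#' Non-targeting control (NTC) guides carry this literal in the \code{gene}
#' column of a \linkS4class{GuideLibrary} and are the anchor of the empirical
#' null in screen scoring.
#'
#' @export
NTC_SENTINEL <- "NTC"

.DNA_ALPHABET <- c("A", "C", "G", "T")

## ---------------------------------------------------------------- GuideLibrary

#' GuideLibrary: an sgRNA library
#'
#' Container for a pooled CRISPR library: one row per guide with a unique
#' guide id, the targeted gene symbol (or the \code{\link{NTC_SENTINEL}}) and
#' a fixed-length DNA spacer. Mirrors the composition of a Brunello-style
#' genome-wide library (about 4 guides per gene plus 1000 non-targeting
#' controls).
#'
#' @slot guides A \link[S4Vectors]{DataFrame} with columns \code{guide_id},
#'   \code{gene}, \code{spacer}.
#'
#' @seealso \code{\link{generateLibrary}}, \code{\link{readGuideLibrary}}
#' @export
setClass("GuideLibrary", slots = c(guides = "DataFrame"))

setValidity("GuideLibrary", function(object) {
    g <- object@guides
    msg <- character()
    need <- c("guide_id", "gene", "spacer")
    if (!all(need %in% colnames(g)))
        return(paste("guides must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(g$guide_id))
        msg <- c(msg, "guide_ids must be unique")
    if (nrow(g) > 0) {
        if (anyDuplicated(g$spacer))
            msg <- c(msg, "spacers must be unique")
        len <- unique(nchar(g$spacer))
        if (length(len) > 1)
            msg <- c(msg, "all spacers must have the same length")
        if (any(grepl("[^ACGT]", g$spacer)))
            msg <- c(msg, "spacer alphabet must be A/C/G/T")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GuideLibrary from its columns
#'
#' @param guide_id Character vector of unique guide ids.
#' @param gene Character vector of gene symbols; non-targeting controls carry
#'   \code{\link{NTC_SENTINEL}}.
#' @param spacer Character vector of equal-length A/C/G/T spacers.
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' GuideLibrary(c("g1", "g2"), c("TP53", "NTC"), c("ACGT", "TTTT"))
#' @export
GuideLibrary <- function(guide_id, gene, spacer) {
    new("GuideLibrary", guides = DataFrame(
        guide_id = as.character(guide_id),
        gene = as.character(gene),
        spacer = as.character(spacer)))
}

#' @describeIn GuideLibrary Number of guides.
#' @param x A \linkS4class{GuideLibrary}.
#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@guides))

#' @rdname guideIds
#' @export
setMethod("guideIds", "GuideLibrary", function(x) x@guides$guide_id)

#' @rdname spacers
#' @export
setMethod("spacers", "GuideLibrary", function(x) {
    s <- Biostrings::DNAStringSet(x@guides$spacer)
    names(s) <- x@guides$guide_id
    s
})

#' @rdname isNTC
#' @export
setMethod("isNTC", "GuideLibrary", function(x) x@guides$gene == NTC_SENTINEL)

#' @rdname targetGenes
#' @export
setMethod("targetGenes", "GuideLibrary",
    function(x) unique(x@guides$gene[x@guides$gene != NTC_SENTINEL]))

#' Genes of each guide
#'
#' @param x A \linkS4class{GuideLibrary}.
#' @return Character vector, parallel to \code{guideIds(x)}.
#' @export
guideGenes <- function(x) {
    stopifnot(is(x, "GuideLibrary"))
    x@guides$gene
}

setMethod("show", "GuideLibrary", function(object) {
    nt <- sum(!isNTC(object))
    cat("GuideLibrary with", length(object), "guides:",
        nt, "targeting", paste0("(", length(targetGenes(object)), " genes),"),
        length(object) - nt, "non-targeting\n")
})

## ----------------------------------------------------------------- ScreenTruth

#' ScreenTruth: planted ground truth of a synthetic screen
#'
#' Holds the generative parameters the screen is asked to recover: per-gene
#' additive shifts in the log-odds that a cell forms a reporter inclusion,
#' per-guide knockout efficacies, and the baseline inclusion log-odds of an
#' unperturbed cell.
#'
#' @slot library The \linkS4class{GuideLibrary}.
#' @slot geneEffect Named numeric: log-odds shift per gene (NTC sentinel is 0).
#' @slot guideEfficacy Named numeric in [0, 1] per guide.
#' @slot baseLogit Numeric scalar baseline log-odds.
#'
#' @seealso \code{\link{assignEffects}}
#' @export
setClass("ScreenTruth", slots = c(
    library = "GuideLibrary",
    geneEffect = "numeric",
    guideEfficacy = "numeric",
    baseLogit = "numeric"))

setValidity("ScreenTruth", function(object) {
    msg <- character()
    if (NTC_SENTINEL %in% names(object@geneEffect) &&
        object@geneEffect[[NTC_SENTINEL]] != 0)
        msg <- c(msg, "NTC sentinel effect must be exactly 0")
    if (any(object@guideEfficacy < 0 | object@guideEfficacy > 1))
        msg <- c(msg, "guide efficacies must lie in [0, 1]")
    if (!setequal(names(object@guideEfficacy), guideIds(object@library)))
        msg <- c(msg, "every library guide needs an efficacy")
    if (length(object@baseLogit) != 1L)
        msg <- c(msg, "baseLogit must be a single number")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @rdname geneEffects
#' @export
setMethod("geneEffects", "ScreenTruth", function(x) x@geneEffect)

#' @rdname guideEfficacies
#' @export
setMethod("guideEfficacies", "ScreenTruth", function(x) x@guideEfficacy)

#' @rdname baseLogit
#' @export
setMethod("baseLogit", "ScreenTruth", function(x) x@baseLogit)

#' @rdname guideLibrary
#' @export
setMethod("guideLibrary", "ScreenTruth", function(x) x@library)

setMethod("show", "ScreenTruth", function(object) {
    e <- object@geneEffect[names(object@geneEffect) != NTC_SENTINEL]
    cat("ScreenTruth:", sum(e > 0), "positive,", sum(e < 0),
        "negative regulators among", length(e), "genes;",
        sprintf("baseline inclusion probability %.3f\n",
                stats::plogis(object@baseLogit)))
})

## -------------------------------------------------------------- CellPopulation

#' CellPopulation: single-guide cells with latent inclusion state
#'
#' One row per cell: the guide it carries (single integration, low MOI),
#' whether the knockout succeeded, the reporter expression level, whether the
#' cell formed an inclusion, and the latent fraction of reporter fluorescence
#' concentrated in the inclusion (0 for diffuse cells).
#'
#' @slot cells A \link[S4Vectors]{DataFrame} with columns \code{cell_id},
#'   \code{guide_id}, \code{ko_success}, \code{total_fluorescence},
#'   \code{aggregated}, \code{punctate_fraction}.
#' @slot library The \linkS4class{GuideLibrary} the guides come from.
#'
#' @seealso \code{\link{simulatePopulation}}
#' @export
setClass("CellPopulation", slots = c(cells = "DataFrame",
                                     library = "GuideLibrary"))

setValidity("CellPopulation", function(object) {
    d <- object@cells
    msg <- character()
    need <- c("cell_id", "guide_id", "ko_success", "total_fluorescence",
              "aggregated", "punctate_fraction")
    if (!all(need %in% colnames(d)))
        return(paste("cells must have columns", paste(need, collapse = ", ")))
    if (nrow(d) > 0) {
        if (any(d$total_fluorescence <= 0))
            msg <- c(msg, "total_fluorescence must be > 0")
        if (!all((d$punctate_fraction > 0) == d$aggregated))
            msg <- c(msg, "punctate_fraction > 0 iff aggregated")
        if (any(d$punctate_fraction < 0 | d$punctate_fraction > 1))
            msg <- c(msg, "punctate_fraction must lie in [0, 1]")
        if (!all(d$guide_id %in% guideIds(object@library)))
            msg <- c(msg, "every cell's guide must exist in the library")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @rdname cells
#' @export
setMethod("cells", "CellPopulation", function(x) x@cells)

#' @rdname guideLibrary
#' @export
setMethod("guideLibrary", "CellPopulation", function(x) x@library)

#' @describeIn CellPopulation Number of cells.
#' @param x A \linkS4class{CellPopulation}.
#' @export
setMethod("length", "CellPopulation", function(x) nrow(x@cells))

setMethod("show", "CellPopulation", function(object) {
    d <- object@cells
    cat("CellPopulation with", nrow(d), "cells;",
        sprintf("aggregated fraction %.3f\n",
                if (nrow(d)) mean(d$aggregated) else NA_real_))
})

## ---------------------------------------------------------------- OpticalModel

#' OpticalModel: cytometer pulse physics
#'
#' Parameters of the pulse model: a cell transits a Gaussian interrogation
#' beam; diffusely distributed fluorophores have a spatial footprint
#' proportional to cell diameter, an inclusion is a near-point source. The
#' recorded pulse is the convolution of the beam with the fluorophore
#' distribution, so the punctate component is taller and narrower than the
#' diffuse one at equal total signal — the contrast PulSA gating exploits.
#'
#' @slot beamSigma Gaussian sigma of the beam (micrometres).
#' @slot cellSigmaFactor Dimensionless: spatial sigma of diffuse fluorophores
#'   = \code{cellSigmaFactor * diameter}.
#' @slot punctumSigma Spatial sigma of an inclusion (micrometres), much
#'   smaller than the beam.
#' @slot diameterMeanlog,diameterSdlog Log-normal cell diameter parameters.
#' @slot scanSpeed Transit speed (micrometres per time unit).
#' @slot triggerThreshold Absolute signal threshold defining pulse width.
#' @slot noiseSd Gaussian noise added to the pulse height (signal units).
#'
#' @seealso \code{\link{acquirePopulation}}
#' @export
setClass("OpticalModel", slots = c(
    beamSigma = "numeric", cellSigmaFactor = "numeric",
    punctumSigma = "numeric", diameterMeanlog = "numeric",
    diameterSdlog = "numeric", scanSpeed = "numeric",
    triggerThreshold = "numeric", noiseSd = "numeric"))

setValidity("OpticalModel", function(object) {
    msg <- character()
    if (object@beamSigma <= 0) msg <- c(msg, "beamSigma must be > 0")
    if (object@punctumSigma < 0) msg <- c(msg, "punctumSigma must be >= 0")
    if (object@triggerThreshold < 0)
        msg <- c(msg, "triggerThreshold must be >= 0")
    if (object@scanSpeed <= 0) msg <- c(msg, "scanSpeed must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an optical model
#'
#' Defaults describe a focused beam (sigma 2 um) narrow relative to a typical
#' 15 um cell, a sub-micrometre inclusion, and a trigger threshold well below
#' typical pulse heights.
#'
#' @param beamSigma,cellSigmaFactor,punctumSigma,diameterMeanlog,diameterSdlog
#'   See \linkS4class{OpticalModel}.
#' @param scanSpeed,triggerThreshold,noiseSd See \linkS4class{OpticalModel}.
#' @return An \linkS4class{OpticalModel}.
#' @examples
#' opticalModel(noiseSd = 0)
#' @export
opticalModel <- function(beamSigma = 2, cellSigmaFactor = 0.3,
                         punctumSigma = 0.5,
                         diameterMeanlog = log(15), diameterSdlog = 0.1,
                         scanSpeed = 1, triggerThreshold = 1, noiseSd = 1) {
    new("OpticalModel", beamSigma = beamSigma,
        cellSigmaFactor = cellSigmaFactor, punctumSigma = punctumSigma,
        diameterMeanlog = diameterMeanlog, diameterSdlog = diameterSdlog,
        scanSpeed = scanSpeed, triggerThreshold = triggerThreshold,
        noiseSd = noiseSd)
}

## ------------------------------------------------------------------- PulseData

#' PulseData: simulated cytometry pulses
#'
#' One record per cell: pulse height (FITC-H analogue), width (FITC-W
#' analogue, time above the trigger threshold), area (total-expression
#' analogue) and the carried-through true aggregation label used only for
#' evaluation.
#'
#' @slot pulses A \link[S4Vectors]{DataFrame} with columns \code{cell_id},
#'   \code{guide_id} (if acquired from a population), \code{height},
#'   \code{width}, \code{area}, \code{truth_aggregated}.
#'
#' @seealso \code{\link{acquirePopulation}}, \code{\link{gateExpression}}
#' @export
setClass("PulseData", slots = c(pulses = "DataFrame"))

setValidity("PulseData", function(object) {
    d <- object@pulses
    need <- c("cell_id", "height", "width", "area", "truth_aggregated")
    if (!all(need %in% colnames(d)))
        return(paste("pulses must have columns", paste(need, collapse = ", ")))
    if (nrow(d) > 0 && any(d$height < 0 | d$width < 0 | d$area < 0))
        return("height, width and area must be >= 0")
    TRUE
})

#' @rdname pulses
#' @export
setMethod("pulses", "PulseData", function(x) x@pulses)

#' @describeIn PulseData Number of pulse records.
#' @param x A \linkS4class{PulseData}.
#' @export
setMethod("length", "PulseData", function(x) nrow(x@pulses))

setMethod("show", "PulseData", function(object) {
    d <- object@pulses
    cat("PulseData with", nrow(d), "records;",
        if (nrow(d)) sprintf("median height %.1f, median width %.1f\n",
                             stats::median(d$height), stats::median(d$width))
        else "\n")
})

## -------------------------------------------------------------------- GateSpec

#' GateSpec: expression and PulSA sort gates
#'
#' The expression gate is a closed quantile interval on pulse area; the
#' aggregate and diffuse gates are thresholds on the pulse-shape discriminant
#' r = height / width, calibrated so that each tail captures a target
#' fraction (the screen collected about 5 percent per tail). Records exactly
#' at a threshold belong to the gate (closed interval).
#'
#' @slot expressionRange Numeric length-2: the [q_lo, q_hi] area quantiles.
#' @slot aggregateMin Minimum discriminant r of the aggregate gate.
#' @slot diffuseMax Maximum discriminant r of the diffuse gate.
#' @slot targetFraction The per-tail capture fraction the gates were
#'   calibrated for.
#'
#' @seealso \code{\link{calibratePulsaGates}}, \code{\link{applyGates}}
#' @export
setClass("GateSpec", slots = c(
    expressionRange = "numeric", aggregateMin = "numeric",
    diffuseMax = "numeric", targetFraction = "numeric"))

setValidity("GateSpec", function(object) {
    msg <- character()
    if (object@targetFraction <= 0 || object@targetFraction > 0.5)
        msg <- c(msg, "targetFraction must lie in (0, 0.5]")
    if (is.finite(object@aggregateMin) && is.finite(object@diffuseMax) &&
        object@diffuseMax >= object@aggregateMin)
        msg <- c(msg, "gates must be disjoint (diffuseMax < aggregateMin)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "GateSpec", function(object) {
    cat(sprintf(
        "GateSpec: aggregate r >= %.4g, diffuse r <= %.4g (target %.1f%%)\n",
        object@aggregateMin, object@diffuseMax, 100 * object@targetFraction))
})

## -------------------------------------------------------------- AmpliconDesign

#' AmpliconDesign: layout of the sgRNA sequencing amplicon
#'
#' Reads are modelled as constant vector sequence flanking the variable
#' spacer: \code{leftFlank + spacer + rightFlank}, truncated or padded to
#' \code{readLength}. Spacer extraction anchors on the first exact occurrence
#' of the left flank. Defaults use the lentiGuide vector sequence immediately
#' upstream of the spacer and the start of the sgRNA scaffold downstream,
#' with the 63-cycle read length used for sgRNA sequencing.
#'
#' @slot leftFlank,rightFlank Constant DNA strings around the spacer.
#' @slot spacerLength Spacer length in nt (20 for Brunello-style libraries).
#' @slot requireRightFlank Whether extraction also checks the right flank.
#' @slot readLength Length of synthesized reads.
#'
#' @seealso \code{\link{extractSpacers}}, \code{\link{synthesizeReads}}
#' @export
setClass("AmpliconDesign", slots = c(
    leftFlank = "character", rightFlank = "character",
    spacerLength = "integer", requireRightFlank = "logical",
    readLength = "integer"))

setValidity("AmpliconDesign", function(object) {
    msg <- character()
    if (!nzchar(object@leftFlank) || grepl("[^ACGT]", object@leftFlank))
        msg <- c(msg, "leftFlank must be a non-empty A/C/G/T string")
    if (!nzchar(object@rightFlank) || grepl("[^ACGT]", object@rightFlank))
        msg <- c(msg, "rightFlank must be a non-empty A/C/G/T string")
    if (object@spacerLength < 1L) msg <- c(msg, "spacerLength must be >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an amplicon design
#'
#' @param leftFlank,rightFlank,spacerLength,requireRightFlank,readLength
#'   See \linkS4class{AmpliconDesign}.
#' @return An \linkS4class{AmpliconDesign}.
#' @examples
#' ampliconDesign(leftFlank = "ACCG", rightFlank = "GTTT", spacerLength = 5L)
#' @export
ampliconDesign <- function(leftFlank = "GGAAAGGACGAAACACCG",
                           rightFlank = "GTTTTAGAGCTAGAAATAGC",
                           spacerLength = 20L,
                           requireRightFlank = TRUE,
                           readLength = 63L) {
    new("AmpliconDesign", leftFlank = leftFlank, rightFlank = rightFlank,
        spacerLength = as.integer(spacerLength),
        requireRightFlank = requireRightFlank,
        readLength = as.integer(readLength))
}

## --------------------------------------------------------------- ScoringConfig

#' ScoringConfig: constants of the screen scoring algorithm
#'
#' Houses the scoring constants: counts are normalized per sample by dividing
#' by the sample mean, multiplying by one million (\code{scale}) and adding
#' one pseudocount; local Z-scores use a 2000-guide window over the abundance
#' ranking; gene p-values use 100,000 permutations of guide-to-gene
#' assignments by default; hits require p below 0.005 and absolute phenotype
#' above 1.
#'
#' @slot pseudocount Added after scaling (default 1).
#' @slot scale Normalization scale (default 1e6).
#' @slot window Local Z window size in guides (default 2000).
#' @slot nPerm Number of permutation draws (default 1e5).
#' @slot logBase Base of the fold-change logarithm (default 2).
#' @slot pThreshold Hit p-value threshold (default 0.005).
#' @slot phenotypeThreshold Hit |phenotype| threshold (default 1).
#' @slot seed Integer seed governing permutation draws.
#' @slot includeNtcInWindow Whether NTC guides enter the abundance ranking
#'   and window statistics (default TRUE).
#' @slot includeNtcInNull Whether NTC guides enter the permutation pool
#'   (default FALSE: targeting guides only).
#' @slot excludeFocal Whether the focal guide is excluded from its own window
#'   statistics (default FALSE: included).
#' @slot exhaustiveCap Enumerate all subsets exactly when their count is at
#'   most this cap, instead of sampling (default 5000).
#' @slot ntcPseudoSize Guides per NTC pseudo-gene (default 4).
#'
#' @seealso \code{\link{scoreScreen}}
#' @export
setClass("ScoringConfig", slots = c(
    pseudocount = "numeric", scale = "numeric", window = "integer",
    nPerm = "integer", logBase = "numeric", pThreshold = "numeric",
    phenotypeThreshold = "numeric", seed = "integer",
    includeNtcInWindow = "logical", includeNtcInNull = "logical",
    excludeFocal = "logical", exhaustiveCap = "numeric",
    ntcPseudoSize = "integer"))

setValidity("ScoringConfig", function(object) {
    msg <- character()
    if (object@window < 2L) msg <- c(msg, "window must be >= 2")
    if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
    if (object@pThreshold <= 0 || object@phenotypeThreshold <= 0)
        msg <- c(msg, "thresholds must be positive")
    if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
    if (object@logBase <= 0 || object@logBase == 1)
        msg <- c(msg, "logBase must be positive and != 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a scoring configuration
#'
#' @param pseudocount,scale,window,nPerm,logBase,pThreshold,phenotypeThreshold
#'   See \linkS4class{ScoringConfig}.
#' @param seed,includeNtcInWindow,includeNtcInNull,excludeFocal,exhaustiveCap
#'   See \linkS4class{ScoringConfig}.
#' @param ntcPseudoSize See \linkS4class{ScoringConfig}.
#' @return A \linkS4class{ScoringConfig}.
#' @examples
#' scoringConfig(window = 200L, nPerm = 1000L)
#' @export
scoringConfig <- function(pseudocount = 1, scale = 1e6, window = 2000L,
                          nPerm = 100000L, logBase = 2, pThreshold = 0.005,
                          phenotypeThreshold = 1, seed = 1L,
                          includeNtcInWindow = TRUE,
                          includeNtcInNull = FALSE,
                          excludeFocal = FALSE,
                          exhaustiveCap = 5000, ntcPseudoSize = 4L) {
    new("ScoringConfig", pseudocount = pseudocount, scale = scale,
        window = as.integer(window), nPerm = as.integer(nPerm),
        logBase = logBase, pThreshold = pThreshold,
        phenotypeThreshold = phenotypeThreshold, seed = as.integer(seed),
        includeNtcInWindow = includeNtcInWindow,
        includeNtcInNull = includeNtcInNull,
        excludeFocal = excludeFocal,
        exhaustiveCap = exhaustiveCap,
        ntcPseudoSize = as.integer(ntcPseudoSize))
}

## ---------------------------------------------------------------- ScreenCounts

#' ScreenCounts: sgRNA count matrix with per-sample QC
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose \code{counts}
#' assay holds non-negative integer sgRNA counts (rows exactly the library's
#' guides, zeros allowed), with guide annotation in \code{rowData} and sample
#' annotation plus counting QC (\code{n_reads}, \code{n_assigned},
#' \code{n_flank_fail}, \code{n_no_match}, \code{n_ambiguous}) in
#' \code{colData}.
#'
#' @seealso \code{\link{countSpacers}}, \code{\link{readCountsTsv}}
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("must have a 'counts' assay")
    m <- SummarizedExperiment::assay(object, "counts")
    if (length(m) > 0 && (any(m < 0) || any(m != round(m))))
        return("counts must be non-negative integers")
    if (is.null(rownames(object)))
        return("rownames must be guide ids")
    TRUE
})

#' @rdname guideIds
#' @export
setMethod("guideIds", "ScreenCounts", function(x) rownames(x))

#' Construct a ScreenCounts object
#'
#' @param counts Integer matrix, guides x samples; rownames are guide ids.
#' @param library Optional \linkS4class{GuideLibrary}; rows are reordered to
#'   the library and missing guides error out.
#' @param colData Optional \link[S4Vectors]{DataFrame} of sample annotation.
#' @return A \linkS4class{ScreenCounts}.
#' @export
ScreenCounts <- function(counts, library = NULL, colData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    rd <- NULL
    if (!is.null(library)) {
        miss <- setdiff(guideIds(library), rownames(counts))
        if (length(miss))
            stop("counts are missing library guides: ",
                 paste(utils::head(miss, 5), collapse = ", "))
        extra <- setdiff(rownames(counts), guideIds(library))
        if (length(extra))
            stop("counts contain guides absent from the library: ",
                 paste(utils::head(extra, 5), collapse = ", "))
        counts <- counts[guideIds(library), , drop = FALSE]
        rd <- library@guides
    }
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = colData)
    if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
    new("ScreenCounts", se)
}

## ---------------------------------------------------------------- ScreenScores

#' ScreenScores: results of screen scoring
#'
#' Bundles the gene-level results (phenotype from the two strongest guides,
#' permutation p-value, hit call), the per-guide statistics (normalized
#' abundances, log fold change, local Z), the NTC pseudo-gene calibration
#' results, and the configuration used.
#'
#' @slot geneResults \link[S4Vectors]{DataFrame}: \code{gene},
#'   \code{n_guides}, \code{phenotype}, \code{mean_z}, \code{p_value},
#'   \code{is_hit}, \code{direction}; sorted by p-value, then decreasing
#'   |phenotype|, then gene.
#' @slot guideStats \link[S4Vectors]{DataFrame} of per-guide statistics.
#' @slot ntcResults \link[S4Vectors]{DataFrame} of NTC pseudo-gene results.
#' @slot config The \linkS4class{ScoringConfig} used.
#'
#' @seealso \code{\link{scoreScreen}}
#' @export
setClass("ScreenScores", slots = c(
    geneResults = "DataFrame", guideStats = "DataFrame",
    ntcResults = "DataFrame", config = "ScoringConfig"))

#' @rdname geneResults
#' @export
setMethod("geneResults", "ScreenScores", function(x) x@geneResults)

#' @rdname guideStats
#' @export
setMethod("guideStats", "ScreenScores", function(x) x@guideStats)

#' @rdname ntcResults
#' @export
setMethod("ntcResults", "ScreenScores", function(x) x@ntcResults)

setMethod("show", "ScreenScores", function(object) {
    g <- object@geneResults
    cat("ScreenScores:", nrow(g), "genes,", sum(g$is_hit), "hits",
        sprintf("(p < %g and |phenotype| > %g)\n",
                object@config@pThreshold, object@config@phenotypeThreshold))
    if (nrow(g)) {
        cat("Top genes:\n")
        print(utils::head(as.data.frame(g), 5))
    }
})
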