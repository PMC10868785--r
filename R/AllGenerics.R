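#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Guide identifiers of an object
#'
#' @param x A \linkS4class{GuideLibrary}, \linkS4class{ScreenTruth} or
#'   \linkS4class{ScreenCounts}.
#' @return Character vector of guide ids.
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' Spacer sequences of a guide library
#'
#' @param x A \linkS4class{GuideLibrary}.
#' @return A \link[Biostrings]{DNAStringSet} named by guide id.
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' Non-targeting-control indicator
#'
#' @param x A \linkS4class{GuideLibrary}.
#' @return Logical vector, \code{TRUE} for guides carrying the NTC sentinel.
#' @export
setGeneric("isNTC", function(x) standardGeneric("isNTC"))

#' Target genes of a library
#'
#' @param x A \linkS4class{GuideLibrary}.
#' @return Character vector of distinct targeting gene symbols (NTC excluded).
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' Planted per-gene effects
#'
#' @param x A \linkS4class{ScreenTruth}.
#' @return Named numeric vector of additive log-odds effects (0 = neutral).
#' @export
setGeneric("geneEffects", function(x) standardGeneric("geneEffects"))

#' Per-guide knockout efficacies
#'
#' @param x A \linkS4class{ScreenTruth}.
#' @return Named numeric vector of probabilities in [0, 1].
#' @export
setGeneric("guideEfficacies", function(x) standardGeneric("guideEfficacies"))

#' Baseline inclusion log-odds
#'
#' @param x A \linkS4class{ScreenTruth}.
#' @return Numeric scalar: log-odds of inclusion formation in an unperturbed
#'   cell.
#' @export
setGeneric("baseLogit", function(x) standardGeneric("baseLogit"))

#' Guide library carried by an object
#'
#' @param x A \linkS4class{ScreenTruth} or \linkS4class{CellPopulation}.
#' @return The \linkS4class{GuideLibrary}.
#' @export
setGeneric("guideLibrary", function(x) standardGeneric("guideLibrary"))

#' Per-cell table of a population
#'
#' @param x A \linkS4class{CellPopulation}.
#' @return A \link[S4Vectors]{DataFrame} with one row per cell.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' Per-cell pulse table
#'
#' @param x A \linkS4class{PulseData}.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{cell_id},
#'   \code{height}, \code{width}, \code{area}, \code{truth_aggregated}.
#' @export
setGeneric("pulses", function(x) standardGeneric("pulses"))

#' Per-gene results table
#'
#' @param x A \linkS4class{ScreenScores}.
#' @return A \link[S4Vectors]{DataFrame} of gene-level results.
#' @export
setGeneric("geneResults", function(x) standardGeneric("geneResults"))

#' Per-guide statistics table
#'
#' @param x A \linkS4class{ScreenScores}.
#' @return A \link[S4Vectors]{DataFrame} of guide-level statistics.
#' @export
setGeneric("guideStats", function(x) standardGeneric("guideStats"))

#' NTC pseudo-gene results table
#'
#' @param x A \linkS4class{ScreenScores}.
#' @return A \link[S4Vectors]{DataFrame} of pseudo-gene results.
#' @export
setGeneric("ntcResults", function(x) standardGeneric("ntcResults"))
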