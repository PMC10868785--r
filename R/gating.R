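#' Gate cells on total expression
#'
#' Keeps pulse records whose area lies in the closed interval between two
#' order statistics of area: the lower bound is the \code{max(1,
#' ceiling(qLo * n))}-th smallest area and the upper bound the
#' \code{ceiling(qHi * n)}-th smallest. This order-statistic convention is
#' normative: with n = 1000 distinct areas 1..1000 and quantiles
#' [0.25, 0.75], areas 250..750 (501 records) are retained. Mirrors sorting
#' within a narrow window of transgene expression to control for expression
#' effects on aggregation.
#'
#' @param pulseData A \linkS4class{PulseData}.
#' @param qLo,qHi Quantile bounds, 0 <= qLo < qHi <= 1.
#' @return A \linkS4class{PulseData} with the retained records, input order
#'   preserved. Empty input yields empty output.
#' @examples
#' pd <- new("PulseData", pulses = S4Vectors::DataFrame(
#'     cell_id = 1:4, height = 1:4, width = rep(1, 4), area = c(1, 2, 3, 4),
#'     truth_aggregated = rep(FALSE, 4)))
#' length(gateExpression(pd, 0.25, 0.75))
#' @export
gateExpression <- function(pulseData, qLo, qHi) {
    stopifnot(is(pulseData, "PulseData"),
              qLo >= 0, qHi <= 1, qLo < qHi)
    d <- pulseData@pulses
    n <- nrow(d)
    if (n == 0) return(pulseData)
    a <- sort(d$area)
    lo <- a[max(1L, ceiling(qLo * n))]
    hi <- a[ceiling(qHi * n)]
    keep <- d$area >= lo & d$area <= hi
    new("PulseData", pulses = d[keep, , drop = FALSE])
}

#' Calibrate PulSA aggregate / diffuse gates
#'
#' Computes thresholds on the pulse-shape discriminant r = height / width so
#' that the aggregate gate (high r: tall, narrow, punctate pulses) and the
#' diffuse gate (low r) each capture \code{round(targetFraction * n)}
#' records, within one, among records with positive width. The screen
#' collected approximately 5 percent of cells per tail. Records with width 0
#' cannot be ranked; they are excluded and counted in the \code{qc}
#' attribute.
#'
#' @param pulseData A \linkS4class{PulseData} (non-empty).
#' @param targetFraction Per-tail capture fraction in (0, 0.5].
#' @return A \linkS4class{GateSpec} with a \code{qc} attribute
#'   (\code{n_width_zero} records excluded from calibration). A target
#'   fraction rounding to 0 records yields empty (infinite) gates.
#' @seealso \code{\link{applyGates}}
#' @export
calibratePulsaGates <- function(pulseData, targetFraction = 0.05) {
    stopifnot(is(pulseData, "PulseData"), length(pulseData) > 0,
              targetFraction > 0, targetFraction <= 0.5)
    d <- pulseData@pulses
    ok <- d$width > 0
    r <- d$height[ok] / d$width[ok]
    n <- length(r)
    k <- round(targetFraction * n)
    if (k == 0) {
        spec <- new("GateSpec", expressionRange = c(0, 1),
                    aggregateMin = Inf, diffuseMax = -Inf,
                    targetFraction = targetFraction)
    } else {
        rs <- sort(r)
        spec <- new("GateSpec", expressionRange = c(0, 1),
                    aggregateMin = rs[n - k + 1L], diffuseMax = rs[k],
                    targetFraction = targetFraction)
    }
    attr(spec, "qc") <- c(n_width_zero = sum(!ok))
    spec
}

#' Apply sort gates to pulse records
#'
#' Splits records into the aggregate gate (r >= \code{aggregateMin}) and the
#' diffuse gate (r <= \code{diffuseMax}), r = height / width. Records exactly
#' at a threshold belong to the gate (closed on the gate side). Records with
#' width 0 have no defined r and fall in neither gate.
#'
#' @param pulseData A \linkS4class{PulseData}.
#' @param gates A \linkS4class{GateSpec}.
#' @return Named list of two \linkS4class{PulseData}: \code{aggregate} and
#'   \code{diffuse}; the subsets are disjoint.
#' @export
applyGates <- function(pulseData, gates) {
    stopifnot(is(pulseData, "PulseData"), is(gates, "GateSpec"))
    d <- pulseData@pulses
    r <- ifelse(d$width > 0, d$height / d$width, NA_real_)
    agg <- !is.na(r) & r >= gates@aggregateMin
    dif <- !is.na(r) & r <= gates@diffuseMax
    list(aggregate = new("PulseData", pulses = d[agg, , drop = FALSE]),
         diffuse = new("PulseData", pulses = d[dif, , drop = FALSE]))
}

#' Aggregation fraction by expression bin
#'
#' Bins records by pulse area (total expression) and reports the fraction of
#' aggregated cells per bin — the analysis showing whether an effect on
#' aggregation is independent of expression level. Bins are
#' \code{[edge_i, edge_{i+1})}, the last bin closed on both sides.
#'
#' @param pulseData A \linkS4class{PulseData}.
#' @param binEdges Strictly increasing numeric vector of area bin edges.
#' @param labels Logical vector of aggregation labels parallel to the
#'   records, or \code{NULL} to use the carried truth labels. Gate-derived
#'   labels can be supplied to analyse sorted data.
#' @return A data.frame with one row per bin: \code{bin_lo}, \code{bin_hi},
#'   \code{n_cells}, \code{fraction_aggregated} (NA for empty bins) and
#'   \code{undefined} flagging empty bins.
#' @examples
#' pd <- new("PulseData", pulses = S4Vectors::DataFrame(
#'     cell_id = 1:4, height = 1, width = 1, area = c(1, 1, 1, 9),
#'     truth_aggregated = c(TRUE, FALSE, FALSE, FALSE)))
#' binnedAggregationFraction(pd, c(0, 5, 10))
#' @export
binnedAggregationFraction <- function(pulseData, binEdges, labels = NULL) {
    stopifnot(is(pulseData, "PulseData"), length(binEdges) >= 2,
              all(diff(binEdges) > 0))
    d <- pulseData@pulses
    if (is.null(labels)) labels <- d$truth_aggregated
    stopifnot(length(labels) == nrow(d))
    bin <- cut(d$area, binEdges, right = FALSE, include.lowest = FALSE)
    ## close the last bin on the right
    bin[d$area == binEdges[length(binEdges)]] <-
        levels(bin)[length(levels(bin))]
    n <- as.integer(table(bin))
    k <- as.integer(tapply(labels, bin, sum, default = 0L))
    data.frame(bin_lo = binEdges[-length(binEdges)],
               bin_hi = binEdges[-1],
               n_cells = n,
               fraction_aggregated = ifelse(n > 0, k / n, NA_real_),
               undefined = n == 0)
}
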