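#' Simulate cytometer pulses for a cell population
#'
#' Models the fluorescence pulse of each cell transiting a Gaussian
#' interrogation beam. The noiseless signal over transit time is a
#' two-component Gaussian mixture centred on the cell: the diffuse component
#' carries weight \code{(1 - f) * F} with temporal sigma
#' \code{sqrt(beam^2 + (cellSigmaFactor * diameter)^2) / scanSpeed}, the
#' punctate component carries weight \code{f * F} with temporal sigma
#' \code{sqrt(beam^2 + punctumSigma^2) / scanSpeed}, where \code{F} is total
#' fluorescence and \code{f} the punctate fraction. Then:
#' \itemize{
#'   \item \code{height} = peak of the noiseless mixture, plus Gaussian noise
#'     (\code{noiseSd}), floored at 0;
#'   \item \code{width} = duration the noiseless signal exceeds the absolute
#'     trigger threshold (0 when the pulse never crosses it, flagged in the
#'     \code{qc} attribute, not an error);
#'   \item \code{area} = time-integral of the noiseless signal, which equals
#'     \code{F / scanSpeed} exactly — area is linear in total fluorescence.
#' }
#' A cell with zero fluorescence yields (0, 0, 0). Because the punctate sigma
#' is much smaller than the diffuse one, punctate cells are taller and
#' narrower at equal total signal; this is the contrast PulSA gating uses.
#'
#' @param population A \linkS4class{CellPopulation}.
#' @param model An \linkS4class{OpticalModel}.
#' @param seed Integer seed (cell diameters and height noise).
#' @return A \linkS4class{PulseData}, one record per cell in input order,
#'   with a \code{qc} attribute on its table listing
#'   \code{n_width_zero} (pulses never crossing the trigger).
#' @examples
#' lib <- generateLibrary(2, 2, 2, seed = 1)
#' pop <- simulatePopulation(assignEffects(lib, seed = 1), 100, seed = 1)
#' pd <- acquirePopulation(pop, opticalModel(noiseSd = 0), seed = 1)
#' pd
#' @export
acquirePopulation <- function(population, model = opticalModel(), seed = 1L) {
    stopifnot(is(population, "CellPopulation"), is(model, "OpticalModel"))
    d <- population@cells
    n <- nrow(d)
    if (n == 0)
        return(new("PulseData", pulses = DataFrame(
            cell_id = integer(), guide_id = character(), height = numeric(),
            width = numeric(), area = numeric(), truth_aggregated = logical())))
    set.seed(seed)
    diam <- stats::rlnorm(n, model@diameterMeanlog, model@diameterSdlog)
    noise <- if (model@noiseSd > 0) stats::rnorm(n, 0, model@noiseSd) else 0
    p <- .pulseShape(d$total_fluorescence, d$punctate_fraction, diam, model)
    height <- pmax(p$height + noise, 0)
    out <- DataFrame(cell_id = d$cell_id, guide_id = d$guide_id,
                     height = height, width = p$width, area = p$area,
                     truth_aggregated = d$aggregated)
    attr(out, "qc") <- c(n_width_zero = sum(p$width == 0 & p$area > 0))
    new("PulseData", pulses = out)
}

#' Pulse of a single cell
#'
#' Convenience scalar form of \code{\link{acquirePopulation}}'s pulse model:
#' computes height, width and area for one cell given its total fluorescence,
#' punctate fraction and diameter (no diameter sampling, optional noise).
#'
#' @param totalFluorescence Total reporter fluorescence (>= 0).
#' @param punctateFraction Fraction of fluorescence in the inclusion, [0, 1].
#' @param diameter Cell diameter (micrometres).
#' @param model An \linkS4class{OpticalModel}.
#' @param seed Integer seed for the height noise (ignored when
#'   \code{noiseSd} is 0).
#' @return Named numeric vector \code{c(height, width, area)}.
#' @examples
#' m <- opticalModel(beamSigma = 1, cellSigmaFactor = 1, punctumSigma = 0,
#'                   noiseSd = 0)
#' simulatePulse(100, 1, diameter = 2, model = m)["height"] /
#'     simulatePulse(100, 0, diameter = 2, model = m)["height"]  # sqrt(5)
#' @export
simulatePulse <- function(totalFluorescence, punctateFraction = 0,
                          diameter = exp(opticalModel()@diameterMeanlog),
                          model = opticalModel(), seed = 1L) {
    stopifnot(totalFluorescence >= 0, punctateFraction >= 0,
              punctateFraction <= 1)
    p <- .pulseShape(totalFluorescence, punctateFraction, diameter, model)
    h <- p$height
    if (model@noiseSd > 0) {
        set.seed(seed)
        h <- max(h + stats::rnorm(1, 0, model@noiseSd), 0)
    }
    c(height = h, width = p$width, area = p$area)
}

## internal: vectorized noiseless pulse shape.
## Signal s(t) = A1 * dnorm(t, 0, s1) + A2 * dnorm(t, 0, s2); height = s(0),
## area = A1 + A2 = F / scanSpeed, width = 2 t* with s(t*) = threshold,
## found by bisection (s is unimodal and even in t).
.pulseShape <- function(F, f, diameter, model) {
    v <- model@scanSpeed
    s1 <- sqrt(model@beamSigma^2 + (model@cellSigmaFactor * diameter)^2) / v
    s2 <- rep_len(sqrt(model@beamSigma^2 + model@punctumSigma^2) / v,
                  length(F))
    A1 <- (1 - f) * F / v
    A2 <- f * F / v
    height <- A1 / (sqrt(2 * pi) * s1) + A2 / (sqrt(2 * pi) * s2)
    area <- A1 + A2
    width <- numeric(length(F))
    thr <- model@triggerThreshold
    live <- which(height > thr & area > 0)
    if (length(live) && thr > 0) {
        width[live] <- 2 * .crossTime(A1[live], s1[live], A2[live], s2[live],
                                      height[live], thr)
    } else if (length(live)) {
        width[live] <- Inf          # threshold 0: signal never reaches 0
    }
    list(height = height, width = width, area = area)
}

## internal: vectorized bisection for the positive t where the mixture equals
## thr; the bracket upper bound makes each component <= thr/2.
.crossTime <- function(A1, s1, A2, s2, h0, thr) {
    sig <- function(t) A1 * stats::dnorm(t, 0, s1) + A2 * stats::dnorm(t, 0, s2)
    bound <- function(A, s) {
        r <- 2 * A / (sqrt(2 * pi) * s * thr)
        s * sqrt(2 * pmax(log(pmax(r, 1)), 0))
    }
    lo <- numeric(length(A1))
    hi <- pmax(bound(A1, s1), bound(A2, s2)) + 1e-9
    for (i in seq_len(64)) {
        mid <- (lo + hi) / 2
        above <- sig(mid) > thr
        lo[above] <- mid[above]
        hi[!above] <- mid[!above]
    }
    (lo + hi) / 2
}

## ------------------------------------------------------------------- pulse IO

#' Read / write pulse records
#'
#' TSV with header \code{cell_id,height,width,area,truth_aggregated} (plus
#' \code{guide_id} when present). Binary FCS files are not supported.
#'
#' @param pulseData A \linkS4class{PulseData}.
#' @param path File path.
#' @return \code{readPulseData} returns a \linkS4class{PulseData};
#'   \code{writePulseData} returns \code{path} invisibly.
#' @export
writePulseData <- function(pulseData, path) {
    stopifnot(is(pulseData, "PulseData"))
    utils::write.table(as.data.frame(pulseData@pulses), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePulseData
#' @export
readPulseData <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t")
    new("PulseData", pulses = DataFrame(d))
}
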