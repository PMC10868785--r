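noiseless <- function(...) opticalModel(noiseSd = 0, ...)

test_that("zero fluorescence yields an all-zero pulse", {
    p <- simulatePulse(0, 0, diameter = 10, model = noiseless())
    expect_identical(unname(p), c(0, 0, 0))
})

test_that("punctate signal is taller and narrower than diffuse", {
    m <- noiseless()
    pd <- simulatePulse(1000, 0.9, diameter = 15, model = m)
    dd <- simulatePulse(1000, 0, diameter = 15, model = m)
    expect_gt(pd["height"], dd["height"])
    expect_lt(pd["width"], dd["width"])
    expect_equal(unname(pd["area"]), unname(dd["area"]))
})

test_that("peak height matches the closed-form Gaussian convolution", {
    ## beam sigma 1, diffuse spatial sigma 2, point-source inclusion:
    ## height ratio punctate/diffuse = sqrt(1 + 4)/sqrt(1 + 0) = sqrt(5)
    m <- opticalModel(beamSigma = 1, cellSigmaFactor = 1, punctumSigma = 0,
                      noiseSd = 0)
    hp <- simulatePulse(500, 1, diameter = 2, model = m)["height"]
    hd <- simulatePulse(500, 0, diameter = 2, model = m)["height"]
    expect_equal(unname(hp / hd), sqrt(5), tolerance = 1e-12)

    ## independent oracle: numeric quadrature of the beam x fluorophore
    ## convolution at the pulse centre
    quadDiffuse <- stats::integrate(
        function(x) stats::dnorm(x, 0, 2) * stats::dnorm(x, 0, 1),
        -Inf, Inf, rel.tol = 1e-12)$value
    quadPunctate <- stats::dnorm(0, 0, 1)          # point source
    expect_lt(abs(hp / hd - quadPunctate / quadDiffuse), 1e-6)
    expect_lt(abs(unname(hd) - 500 * quadDiffuse), 1e-6 * unname(hd))
})

test_that("pulses are linear in fluorescence and conserve area", {
    m <- noiseless()
    lib <- generateLibrary(3, 4, 4, spacerLength = 8, seed = 1)
    pop <- simulatePopulation(assignEffects(lib, seed = 1,
                                            baseLogit = stats::qlogis(0.3)),
                              500, seed = 1)
    pd <- acquirePopulation(pop, m, seed = 9)
    d <- pulses(pd)
    ## area / F identical across cells to 1e-9 relative
    ratio <- d$area / cells(pop)$total_fluorescence
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)

    ## doubling F doubles height and area exactly, width does not shrink
    a <- simulatePulse(800, 0.5, diameter = 12, model = m)
    b <- simulatePulse(1600, 0.5, diameter = 12, model = m)
    expect_equal(unname(b["height"]), 2 * unname(a["height"]),
                 tolerance = 1e-12)
    expect_equal(unname(b["area"]), 2 * unname(a["area"]), tolerance = 1e-12)
    expect_gte(b["width"], a["width"])
})

test_that("height rises and width falls along the punctate grid", {
    m <- noiseless()
    f <- seq(0, 1, length.out = 21)
    p <- vapply(f, function(fi)
        simulatePulse(1000, fi, diameter = 15, model = m), numeric(3))
    expect_true(all(diff(p["height", ]) > 0))
    expect_true(all(diff(p["width", ]) <= 1e-9))
})

test_that("acquisition preserves order, ids and determinism", {
    lib <- generateLibrary(2, 2, 2, spacerLength = 8, seed = 1)
    pop <- simulatePopulation(assignEffects(lib, seed = 1), 50, seed = 2)
    a <- acquirePopulation(pop, opticalModel(), seed = 5)
    b <- acquirePopulation(pop, opticalModel(), seed = 5)
    expect_identical(pulses(a), pulses(b))
    expect_identical(pulses(a)$cell_id, cells(pop)$cell_id)
    empty <- new("CellPopulation",
                 cells = cells(pop)[0, ], library = lib)
    expect_equal(length(acquirePopulation(empty, seed = 1)), 0L)
})

test_that("pulse tables round trip through TSV", {
    pd <- makePulseData(area = c(1, 2, 3), height = c(2, 4, 6),
                        width = c(1, 1, 2),
                        aggregated = c(TRUE, FALSE, TRUE))
    p <- tempfile(fileext = ".tsv")
    writePulseData(pd, p)
    back <- readPulseData(p)
    expect_equal(as.data.frame(pulses(back)), as.data.frame(pulses(pd)))
})
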