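test_that("expression gating follows the order-statistic convention", {
    pd <- makePulseData(area = sample(1:1000))
    expect_equal(length(gateExpression(pd, 0, 1)), 1000L)
    mid <- gateExpression(pd, 0.25, 0.75)
    expect_equal(length(mid), 501L)
    expect_equal(range(pulses(mid)$area), c(250, 750))
    empty <- makePulseData(numeric())
    expect_equal(length(gateExpression(empty, 0.25, 0.75)), 0L)
    expect_error(gateExpression(pd, 0.8, 0.2))
})

test_that("calibrated tail gates capture the target fraction", {
    set.seed(1)
    pd <- makePulseData(area = runif(10000, 500, 1500),
                        height = runif(10000, 10, 100),
                        width = runif(10000, 5, 50))
    gates <- calibratePulsaGates(pd, 0.05)
    got <- applyGates(pd, gates)
    expect_true(abs(length(got$aggregate) - 500) <= 1)
    expect_true(abs(length(got$diffuse) - 500) <= 1)
    ## realized capture within 0.2 percentage points of 5%
    expect_lt(abs(100 * length(got$aggregate) / length(pd) - 5), 0.2)
    ## disjoint
    expect_length(intersect(pulses(got$aggregate)$cell_id,
                            pulses(got$diffuse)$cell_id), 0)

    ## a fraction rounding to zero records leaves both gates empty
    tiny <- makePulseData(area = 1:5, height = 1:5, width = rep(1, 5))
    g0 <- calibratePulsaGates(tiny, 0.05)      # round(0.25) = 0
    got0 <- applyGates(tiny, g0)
    expect_equal(length(got0$aggregate), 0L)
    expect_equal(length(got0$diffuse), 0L)
})

test_that("well-separated clusters gate at perfect purity", {
    ## aggregated cluster has 10x the discriminant of the diffuse one
    n <- 2000
    agg <- rep(c(FALSE, TRUE), times = c(n * 0.9, n * 0.1))
    pd <- makePulseData(area = rep(1000, n),
                        height = ifelse(agg, 100, 10),
                        width = ifelse(agg, 5, 50),
                        aggregated = agg)
    gates <- calibratePulsaGates(pd, 0.05)
    got <- applyGates(pd, gates)
    expect_true(all(pulses(got$aggregate)$truth_aggregated))
    expect_true(all(!pulses(got$diffuse)$truth_aggregated))
})

test_that("width-zero records are excluded and reported, boundaries closed", {
    pd <- makePulseData(area = 1:10, height = 1:10,
                        width = c(0, 0, rep(1, 8)))
    gates <- calibratePulsaGates(pd, 0.25)
    expect_equal(unname(attr(gates, "qc")["n_width_zero"]), 2L)
    got <- applyGates(pd, gates)
    ## width-0 records fall in neither gate
    expect_false(any(c(1, 2) %in% c(pulses(got$aggregate)$cell_id,
                                    pulses(got$diffuse)$cell_id)))
    ## record exactly at a threshold belongs to the gate
    pd2 <- makePulseData(area = 1:4, height = c(1, 2, 3, 4),
                         width = rep(1, 4))
    g2 <- new("GateSpec", expressionRange = c(0, 1), aggregateMin = 4,
              diffuseMax = 1, targetFraction = 0.25)
    got2 <- applyGates(pd2, g2)
    expect_equal(pulses(got2$aggregate)$cell_id, 4L)
    expect_equal(pulses(got2$diffuse)$cell_id, 1L)
    ## infinite thresholds yield empty gates
    gInf <- new("GateSpec", expressionRange = c(0, 1), aggregateMin = Inf,
                diffuseMax = -Inf, targetFraction = 0.05)
    gotInf <- applyGates(pd2, gInf)
    expect_equal(length(gotInf$aggregate) + length(gotInf$diffuse), 0L)
})

test_that("binned aggregation fractions count correctly", {
    pd <- makePulseData(area = c(1, 2, 3, 4, 20),
                        aggregated = c(TRUE, FALSE, FALSE, FALSE, TRUE))
    b <- binnedAggregationFraction(pd, c(0, 5, 10, 25))
    expect_equal(b$n_cells, c(4L, 0L, 1L))
    expect_equal(b$fraction_aggregated[1], 0.25)
    expect_true(is.na(b$fraction_aggregated[2]) && b$undefined[2])
    expect_equal(b$fraction_aggregated[3], 1)
    ## all-aggregated input gives fraction 1 in every non-empty bin
    pdAll <- makePulseData(area = c(1, 6, 21),
                           aggregated = rep(TRUE, 3))
    bAll <- binnedAggregationFraction(pdAll, c(0, 5, 10, 25))
    expect_true(all(bAll$fraction_aggregated[bAll$n_cells > 0] == 1))
    ## gate-derived labels can replace the truth labels
    b2 <- binnedAggregationFraction(pd, c(0, 25),
                                    labels = c(TRUE, TRUE, FALSE, FALSE,
                                               FALSE))
    expect_equal(b2$fraction_aggregated, 0.4)
})
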