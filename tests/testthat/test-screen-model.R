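test_that("generated libraries have the requested composition", {
    lib <- generateLibrary(nGenes = 3, guidesPerGene = 4, nNtc = 2,
                           spacerLength = 8, seed = 1)
    expect_s4_class(lib, "GuideLibrary")
    expect_equal(length(lib), 14L)
    expect_equal(sum(!isNTC(lib)), 12L)
    expect_equal(length(targetGenes(lib)), 3L)
    expect_false(anyDuplicated(guideIds(lib)) > 0)
    expect_false(anyDuplicated(as.character(spacers(lib))) > 0)
    expect_true(all(Biostrings::width(spacers(lib)) == 8))

    ntcOnly <- generateLibrary(nGenes = 0, guidesPerGene = 4, nNtc = 5,
                               spacerLength = 6, seed = 1)
    expect_equal(length(ntcOnly), 5L)
    expect_true(all(isNTC(ntcOnly)))
})

test_that("library generation is seed-deterministic and guards spacer space", {
    a <- generateLibrary(10, 4, 5, spacerLength = 10, seed = 42)
    b <- generateLibrary(10, 4, 5, spacerLength = 10, seed = 42)
    expect_identical(a@guides, b@guides)
    c <- generateLibrary(10, 4, 5, spacerLength = 10, seed = 43)
    expect_false(identical(as.character(spacers(a)),
                           as.character(spacers(c))))
    ## 4^2 = 16 < 45 guides
    expect_error(generateLibrary(10, 4, 5, spacerLength = 2, seed = 1),
                 "too small")
})

test_that("planted effects have the requested sign structure", {
    lib <- generateLibrary(100, 4, 20, spacerLength = 10, seed = 1)
    truth <- assignEffects(lib, nUp = 10, nDown = 5, seed = 7)
    eff <- geneEffects(truth)
    targ <- eff[names(eff) != NTC_SENTINEL]
    expect_equal(sum(targ > 0), 10L)
    expect_equal(sum(targ < 0), 5L)
    expect_equal(sum(targ == 0), 85L)
    expect_identical(unname(eff[NTC_SENTINEL]), 0)
    expect_true(all(guideEfficacies(truth) >= 0 &
                    guideEfficacies(truth) <= 1))
    expect_equal(sort(names(guideEfficacies(truth))), sort(guideIds(lib)))

    null <- assignEffects(lib, nUp = 0, nDown = 0, seed = 1)
    expect_true(all(geneEffects(null) == 0))
    expect_error(assignEffects(lib, nUp = 90, nDown = 20, seed = 1),
                 "targeting genes")
})

test_that("population aggregation follows the logistic model", {
    lib <- generateLibrary(5, 4, 10, spacerLength = 8, seed = 1)
    ## degenerate baseline: essentially zero inclusion probability
    never <- assignEffects(lib, baseLogit = -20, seed = 1)
    pop0 <- simulatePopulation(never, 10000, seed = 1)
    expect_equal(sum(cells(pop0)$aggregated), 0L)

    ## baseline 0.2: observed fraction within 3 binomial SDs
    base <- assignEffects(lib, baseLogit = stats::qlogis(0.2), seed = 1)
    pop <- simulatePopulation(base, 50000, seed = 2)
    frac <- mean(cells(pop)$aggregated)
    tol <- 3 * sqrt(0.2 * 0.8 / 50000)
    expect_lt(abs(frac - 0.2), tol)

    ## punctate fraction is positive exactly for aggregated cells
    d <- cells(pop)
    expect_true(all((d$punctate_fraction > 0) == d$aggregated))
    expect_true(all(d$total_fluorescence > 0))

    ## seeded determinism
    pop2 <- simulatePopulation(base, 50000, seed = 2)
    expect_identical(cells(pop), cells(pop2))
})

test_that("a positive regulator raises the aggregated fraction above NTC", {
    lib <- generateLibrary(1, 4, 4, spacerLength = 8, seed = 1)
    truth <- assignEffects(lib, nUp = 1,
                           magnitudeSampler = function(n) rep(2, n),
                           efficacySampler = function(n) rep(1, n),
                           baseLogit = stats::qlogis(0.1), seed = 1)
    pop <- simulatePopulation(truth, 20000, guideAbundanceSpread = 0,
                              seed = 3)
    d <- cells(pop)
    targ <- d$aggregated[!d$guide_id %in% grep("^NTC", d$guide_id,
                                               value = TRUE)]
    ntc <- d$aggregated[startsWith(d$guide_id, "NTC")]
    tst <- stats::prop.test(c(sum(targ), sum(ntc)),
                            c(length(targ), length(ntc)),
                            alternative = "greater")
    expect_lt(tst$p.value, 1e-6)
    ## NTC fraction stays near the baseline
    expect_lt(abs(mean(ntc) - 0.1),
              3 * sqrt(0.1 * 0.9 / length(ntc)))
})

test_that("even libraries at 1000x coverage represent every guide", {
    lib <- generateLibrary(5, 4, 0, spacerLength = 8, seed = 1)
    truth <- assignEffects(lib, seed = 1)
    pop <- simulatePopulation(truth, 1000 * length(lib),
                              guideAbundanceSpread = 0, seed = 4)
    tal <- tallyGuides(pop)
    expect_true(all(tal > 0))
    expect_lt(max(tal) / min(tal), 1.5)
})

test_that("library files round trip through CSV and TSV", {
    lib <- generateLibrary(4, 3, 6, spacerLength = 9, seed = 5)
    for (ext in c(".csv", ".tsv")) {
        p <- tempfile(fileext = ext)
        writeGuideLibrary(lib, p)
        back <- readGuideLibrary(p)
        expect_identical(lib@guides, back@guides)
    }
})
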