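test_that("normalization reproduces the printed formula exactly", {
    expect_equal(normalizeCounts(c(20, 20, 20)), rep(1000001, 3))
    expect_equal(normalizeCounts(c(10, 20, 30)),
                 c(500001, 1000001, 1500001))
    expect_equal(normalizeCounts(c(0, 10))[1], 1)   # zero count -> pseudocount
    expect_error(normalizeCounts(c(0, 0, 0)), "all-zero")
    ## scale invariance: positive rescaling of a sample changes nothing
    x <- c(3, 17, 40, 0, 251)
    expect_equal(normalizeCounts(x), normalizeCounts(7 * x))
    ## matrix form is per-column
    m <- cbind(a = c(10, 20, 30), b = c(20, 20, 20))
    expect_equal(normalizeCounts(m)[, "a"], c(500001, 1000001, 1500001))
})

test_that("log fold changes are exact and antisymmetric", {
    expect_equal(guideLfc(2000002, 1000001), 1)
    expect_equal(guideLfc(1000001, 2000002), -1)
    expect_equal(guideLfc(c(5, 9), c(5, 9)), c(0, 0))
    expect_error(guideLfc(1:3, 1:2), "length")
    cfg10 <- scoringConfig(logBase = 10)
    expect_equal(guideLfc(1000, 100, cfg10), 1)
})

test_that("local Z matches the hand-computed window fixture", {
    ## ranked lfc (0,0,0,4), window 4: every window is the full array,
    ## mean 1, sample SD 2
    z <- localZ(c(0, 0, 0, 4), c(1, 2, 3, 4), window = 4)
    expect_equal(z, c(-0.5, -0.5, -0.5, 1.5))
    ## constant vector: SD-zero rule
    expect_equal(localZ(rep(2, 10), 1:10, window = 4), rep(0, 10))
    ## window larger than n clamps with a warning
    expect_warning(z2 <- localZ(c(0, 0, 0, 4), c(1, 2, 3, 4), window = 10),
                   "window")
    expect_equal(z2, c(-0.5, -0.5, -0.5, 1.5))
    expect_error(localZ(1, 1, window = 2), "at least 2")
    ## output is reported in input order, not rank order
    set.seed(1)
    lfc <- rnorm(50); ab <- runif(50)
    ord <- order(ab)
    expect_equal(localZ(lfc, ab, 10)[ord], localZ(lfc[ord], ab[ord], 10))
})

test_that("vectorized local Z equals the naive double-loop oracle", {
    set.seed(42)
    n <- 3000
    lfc <- rnorm(n, 0, 1.5)
    ab <- rlnorm(n, 5, 1)
    for (w in c(10, 501, 2000)) {
        expect_lt(max(abs(localZ(lfc, ab, w) - naiveLocalZ(lfc, ab, w))),
                  1e-10)
    }
    ## tie-broken ranking agrees too
    abTie <- rep(1:300, each = 10)
    ids <- sprintf("g%04d", sample(n))
    expect_lt(max(abs(localZ(lfc, abTie, 100, guideIds = ids) -
                      naiveLocalZ(lfc, abTie, 100, ids = ids))), 1e-10)
})

test_that("gene phenotype averages the two strongest guides", {
    ph <- genePhenotype(c(0.1, -3.0, 2.5, 0.2), rep("G", 4))
    expect_equal(ph$phenotype, -0.25)
    expect_equal(ph$n_guides, 4L)
    expect_equal(genePhenotype(rep(0, 4), rep("G", 4))$phenotype, 0)
    single <- genePhenotype(1.7, "S")
    expect_equal(single$phenotype, 1.7)
    expect_equal(single$n_guides, 1L)
    ## per-gene grouping
    ph2 <- genePhenotype(c(1, 2, -5, 0.5), c("A", "A", "B", "B"))
    expect_equal(ph2$phenotype, c(1.5, -2.25))
    expect_error(genePhenotype(numeric(), character()))
})

test_that("permutation p-values are exact in exhaustive mode", {
    ## pool (1,2,3), gene owns {2,3}: null means 1.5, 2, 2.5 -> p = 1/3
    expect_equal(unname(genePvalue(c(2, 3), c("G", "G"),
                                   pool = c(1, 2, 3))), 1 / 3)
    ## identical z everywhere: p = 1 for every gene
    p1 <- genePvalue(rep(2, 6), rep(c("A", "B"), each = 3),
                     pool = rep(2, 10))
    expect_true(all(p1 == 1))
    ## sampled floor is 1/(nPerm + 1)
    cfg <- scoringConfig(nPerm = 99L, exhaustiveCap = 0, seed = 5L)
    z <- c(100, 100, rnorm(50))
    g <- c("HIT", "HIT", paste0("N", seq_len(50)))
    p <- genePvalue(z, g, config = cfg)
    expect_equal(unname(p["HIT"]), 1 / 100)
    expect_error(genePvalue(1:3, c("A", "A", "A"), pool = 1:2), "pool")
})

test_that("sampled p-values converge to the exhaustive tail fraction", {
    set.seed(7)
    pool <- rnorm(12)
    z <- pool[c(2, 5, 9)]
    g <- rep("G", 3)
    exact <- genePvalue(z, g, pool = pool,
                        config = scoringConfig(exhaustiveCap = 1000))
    sampled <- genePvalue(z, g, pool = pool,
                          config = scoringConfig(exhaustiveCap = 0,
                                                 nPerm = 50000L, seed = 2L))
    expect_lt(abs(exact - sampled), 0.02)
})

test_that("replicate aggregation averages aligned guide statistics", {
    d1 <- data.frame(guide_id = c("a", "b"), gene = c("G1", "G2"),
                     norm_pos = c(10, 20), norm_neg = c(10, 10),
                     mean_abundance = c(10, 15), lfc = c(0, 1),
                     local_z = c(1, 2))
    expect_equal(as.data.frame(aggregateReplicates(list(d1))), d1)
    expect_equal(as.data.frame(aggregateReplicates(list(d1, d1))), d1)
    d2 <- d1[2:1, ]                      # same guides, different order
    d2$local_z <- c(4, 3)                # b = 4, a = 3
    comb <- aggregateReplicates(list(d1, d2))
    expect_equal(comb$local_z, c(2, 3))  # a: (1+3)/2, b: (2+4)/2
    d3 <- d1; d3$guide_id <- c("a", "zzz")
    expect_error(aggregateReplicates(list(d1, d3)), "differs")
})

test_that("hit calling applies both thresholds with direction", {
    r <- data.frame(gene = c("A", "B", "C", "D"),
                    p_value = c(0.004, 0.004, 0.5, 0.001),
                    phenotype = c(1.2, 0.5, 3.0, -2))
    r <- callHits(r)
    expect_equal(r$is_hit, c(TRUE, FALSE, FALSE, TRUE))
    expect_equal(r$direction, c(1L, 1L, 1L, -1L))
})

test_that("NTC pseudo-genes partition and calibrate uniformly", {
    set.seed(11)
    zNtc <- rnorm(1000)
    pool <- rnorm(8000)
    cfg <- scoringConfig(nPerm = 10000L, seed = 3L)
    res <- ntcPseudogenes(zNtc, pool = pool, config = cfg)
    expect_equal(nrow(res), 250L)
    ## null-simulated data: pseudo-gene p-values look uniform
    ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_error(ntcPseudogenes(rnorm(3), pool = pool, config = cfg),
                 "pseudo-gene")
})

test_that("scoreScreen recovers a planted gene and is deterministic", {
    lib <- generateLibrary(100, 4, 100, spacerLength = 10, seed = 21)
    sc <- plantedCounts(lib, gene = "GENE00050", fold = 4, seed = 22)
    cfg <- scoringConfig(window = 100L, nPerm = 2000L, seed = 4L)
    res <- scoreScreen(sc, lib, cfg)
    g <- as.data.frame(geneResults(res))
    expect_equal(g$gene[1], "GENE00050")
    expect_true(g$is_hit[1])
    expect_equal(unname(g$p_value[1]), 1 / 2001)
    ## deterministic rerun
    res2 <- scoreScreen(sc, lib, cfg)
    expect_identical(as.data.frame(geneResults(res2)), g)
    ## guide stats carry the invariant mean_abundance definition
    gs <- as.data.frame(guideStats(res))
    expect_equal(gs$mean_abundance, (gs$norm_pos + gs$norm_neg) / 2)
    expect_true(all(gs$norm_pos >= cfg@pseudocount))
})

test_that("permuting guide labels destroys a planted signal", {
    lib <- generateLibrary(100, 4, 0, spacerLength = 10, seed = 31)
    sc <- plantedCounts(lib, gene = "GENE00010", fold = 4,
                        nReplicates = 1L, seed = 32)
    cfg <- scoringConfig(window = 100L, nPerm = 1000L, seed = 5L)
    m <- SummarizedExperiment::assay(sc, "counts")
    real <- scoreScreen(sc, lib, cfg)
    gReal <- as.data.frame(geneResults(real))
    expect_lt(gReal$p_value[gReal$gene == "GENE00010"], 0.005)
    broken <- 0L
    nPermLab <- 20L
    for (k in seq_len(nPermLab)) {
        set.seed(1000 + k)
        shuf <- lib
        shuf@guides$gene <- sample(shuf@guides$gene)
        res <- scoreScreen(sc, shuf, cfg)
        g <- as.data.frame(geneResults(res))
        if (g$p_value[g$gene == "GENE00010"] > 0.05) broken <- broken + 1L
    }
    expect_gte(broken, ceiling(0.95 * nPermLab))
})
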