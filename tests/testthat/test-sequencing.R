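test_that("spacer extraction anchors on the left flank", {
    des <- tinyDesign()
    ex <- extractSpacers(c("ACCGAAGGTGTTT",       # clean
                           "TTTTTTTTTTTTT",       # no anchor
                           "NNACCGAAGGTGTTT",     # anchor at offset 2
                           "ACCGAAG",             # spacer cut short
                           "ACCGAAGGTCAAA"),      # wrong right flank
                         des)
    expect_equal(ex$spacer, c("AAGGT", NA, "AAGGT", NA, NA))
    expect_equal(as.character(ex$status),
                 c("ok", "flank_not_found", "ok", "truncated",
                   "right_flank_mismatch"))
    ## right flank check off: mismatch becomes acceptable
    desNoR <- ampliconDesign("ACCG", "GTTT", 5L, requireRightFlank = FALSE)
    ex2 <- extractSpacers("ACCGAAGGTCAAA", desNoR)
    expect_equal(ex2$spacer, "AAGGT")
})

test_that("read synthesis hits the requested depth and round trips", {
    lib <- tinyLibrary()
    des <- tinyDesign()
    expect_length(synthesizeReads(c(g1 = 1), lib, des, 0), 0)
    expect_error(synthesizeReads(c(g1 = 0, g2 = 0), lib, des, 5),
                 "all-zero")

    rd <- synthesizeReads(c(g1 = 2, g2 = 1), lib, des, 3, exact = TRUE)
    expect_length(rd, 3)
    got <- countSpacers(rd, lib, des)
    expect_equal(got$counts, c(g1 = 2L, g2 = 1L))

    rd2 <- synthesizeReads(c(g1 = 5, g2 = 5), lib, des, 1000, seed = 3)
    expect_length(rd2, 1000)
    ## determinism
    rd3 <- synthesizeReads(c(g1 = 5, g2 = 5), lib, des, 1000, seed = 3)
    expect_identical(as.character(rd2), as.character(rd3))
})

test_that("counting applies the Hamming-1 rule and partitions QC", {
    lib <- tinyLibrary()
    des <- tinyDesign()
    mk <- function(spacer) paste0("ACCG", spacer, "GTTTA")
    reads <- c(mk("AAGGT"), mk("AAGGT"), mk("CCCTA"),  # exact
               mk("AAGGA"),                            # 1 mm from g1 only
               mk("GGGGG"),                            # no match
               "TTTTTTTTTTTTTT")                       # flank fail
    got0 <- countSpacers(reads, lib, des, maxMismatch = 0)
    expect_equal(got0$counts, c(g1 = 2L, g2 = 1L))
    expect_equal(unname(got0$qc["n_no_match"]), 2L)

    got1 <- countSpacers(reads, lib, des, maxMismatch = 1)
    expect_equal(got1$counts, c(g1 = 3L, g2 = 1L))
    qc <- got1$qc
    expect_equal(unname(qc["n_reads"]),
                 unname(qc["n_assigned"] + qc["n_flank_fail"] +
                        qc["n_no_match"] + qc["n_ambiguous"]))

    ## ambiguous: equidistant from two library spacers is dropped
    lib2 <- GuideLibrary(c("g1", "g2"), c("A", "B"), c("AAGGT", "AAGGG"))
    gotA <- countSpacers(mk("AAGGC"), lib2, des, maxMismatch = 1)
    expect_equal(sum(gotA$counts), 0L)
    expect_equal(unname(gotA$qc["n_ambiguous"]), 1L)

    ## zero reads: all-zero column, zero QC
    gotZ <- countSpacers(character(), lib, des)
    expect_true(all(gotZ$counts == 0))
    expect_true(all(gotZ$qc == 0))
})

test_that("assigned fraction under sequencing errors matches theory", {
    lib <- generateLibrary(25, 4, 0, spacerLength = 20, seed = 8)
    des <- ampliconDesign()
    tal <- setNames(rep(10, length(lib)), guideIds(lib))
    eps <- 0.01
    depth <- 20000
    rd <- synthesizeReads(tal, lib, des, depth, errorRate = eps, seed = 9)
    got <- countSpacers(rd, lib, des, maxMismatch = 0)
    ## a read survives exact matching iff flanks and spacer are error-free
    nErrorable <- nchar(des@leftFlank) + des@spacerLength +
        nchar(des@rightFlank)
    pClean <- (1 - eps)^nErrorable
    obs <- got$qc["n_assigned"] / depth
    expect_lt(abs(obs - pClean), 3 * sqrt(pClean * (1 - pClean) / depth))
    expect_equal(unname(got$qc["n_reads"]),
                 unname(sum(got$qc[c("n_assigned", "n_flank_fail",
                                     "n_no_match", "n_ambiguous")])))
})

test_that("FASTQ files round trip, plain and gzipped", {
    lib <- tinyLibrary()
    des <- tinyDesign()
    rd <- synthesizeReads(c(g1 = 3, g2 = 2), lib, des, 5, exact = TRUE)
    for (ext in c(".fastq", ".fastq.gz")) {
        p <- tempfile(fileext = ext)
        writeFastq(rd, p)
        back <- readFastq(p)
        expect_equal(as.character(back), as.character(rd),
                     ignore_attr = TRUE)
    }
})

test_that("count tables round trip through TSV and reject bad cells", {
    m <- matrix(c(5L, 0L, 2L, 7L), 2,
                dimnames = list(c("g1", "g2"), c("pos_rep1", "neg_rep1")))
    p <- tempfile(fileext = ".tsv")
    writeCountsTsv(m, p)
    back <- readCountsTsv(p)
    expect_equal(SummarizedExperiment::assay(back, "counts"), m)

    ## 0-sample matrix still round trips
    m0 <- matrix(integer(), nrow = 2, ncol = 0,
                 dimnames = list(c("g1", "g2"), NULL))
    p0 <- tempfile(fileext = ".tsv")
    writeCountsTsv(m0, p0)
    expect_equal(dim(readCountsTsv(p0)), c(2L, 0L))

    neg <- m; neg[1, 1] <- -3L
    pn <- tempfile(fileext = ".tsv")
    writeCountsTsv(neg, pn)
    expect_error(readCountsTsv(pn), "negative")

    bad <- readLines(p)
    bad[2] <- sub("5", "five", bad[2])
    pb <- tempfile(fileext = ".tsv")
    writeLines(bad, pb)
    expect_error(readCountsTsv(pb), "row")
})
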