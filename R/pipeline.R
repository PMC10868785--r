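#' Default run configuration
#'
#' Nested configuration of the full synthetic screen pipeline. Defaults
#' anchor to the screen's printed constants where they exist — 4 guides per
#' gene, 1000 non-targeting controls, 20-nt spacers, about 5 percent of
#' cells collected per sort tail, a 2000-guide local-Z window, 100,000
#' permutations, hit thresholds p < 0.005 and |phenotype| > 1, two
#' (technical) replicates, 63-nt reads — and to documented synthetic
#' choices elsewhere (see the package vignette).
#'
#' @return A nested list with sections \code{screen_model}, \code{optics},
#'   \code{gates}, \code{sequencing}, \code{scoring} and a master
#'   \code{seed}.
#' @examples
#' str(defaultRunConfig(), max.level = 2)
#' @export
defaultRunConfig <- function() {
    list(
        seed = 1L,
        screen_model = list(
            n_genes = 2000L, guides_per_gene = 4L, n_ntc = 1000L,
            spacer_length = 20L,
            n_up = 25L, n_down = 25L,
            effect_magnitude = 4, efficacy = 1,
            base_p = 0.25,
            cells_per_guide = 1000L,
            guide_abundance_spread = 0.5, expression_spread = 0.5,
            mean_fluorescence = 1000),
        optics = list(
            beam_sigma = 2, cell_sigma_factor = 0.3, punctum_sigma = 0.5,
            diameter_meanlog = log(15), diameter_sdlog = 0.1,
            scan_speed = 1, trigger_threshold = 1, noise_sd = 1),
        gates = list(
            expression_q = c(0.25, 0.75), target_fraction = 0.05),
        sequencing = list(
            mode = "counts", reads_per_guide = 500L, error_rate = 0.001,
            n_replicates = 2L),
        scoring = list(
            pseudocount = 1, scale = 1e6, window = 2000L, n_perm = 100000L,
            log_base = 2, p_threshold = 0.005, phenotype_threshold = 1,
            include_ntc_in_window = TRUE, include_ntc_in_null = FALSE,
            ntc_pseudo_size = 4L))
}

#' Read and validate a run configuration
#'
#' Loads YAML (default) or JSON (by extension), overlays it on the defaults
#' and validates: unknown keys are rejected, and each section is checked
#' against its module's constraints before any stage runs.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file, or
#'   \code{NULL} for the defaults.
#' @param overrides Optional nested list applied on top (used
#'   programmatically).
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = NULL) {
    cfg <- defaultRunConfig()
    if (!is.null(path)) {
        user <- if (grepl("\\.json$", path)) {
            jsonlite::read_json(path, simplifyVector = TRUE)
        } else yaml::read_yaml(path)
        cfg <- .mergeConfig(cfg, user, "config")
    }
    if (!is.null(overrides)) cfg <- .mergeConfig(cfg, overrides, "overrides")
    validateRunConfig(cfg)
    cfg
}

## internal: recursive overlay rejecting unknown keys
.mergeConfig <- function(base, user, where) {
    if (is.null(user)) return(base)
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
        stop("unknown key(s) in ", where, ": ",
             paste(unknown, collapse = ", "))
    for (k in names(user)) {
        base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
            .mergeConfig(base[[k]], user[[k]], paste0(where, "$", k))
        else user[[k]]
    }
    base
}

#' @rdname readRunConfig
#' @param config A configuration list.
#' @export
validateRunConfig <- function(config) {
    sm <- config$screen_model
    stopifnot(sm$n_genes >= 0, sm$guides_per_gene >= 0, sm$n_ntc >= 0,
              sm$spacer_length >= 1,
              sm$n_up + sm$n_down <= max(sm$n_genes, 0),
              sm$base_p > 0, sm$base_p < 1, sm$cells_per_guide >= 1,
              sm$efficacy >= 0, sm$efficacy <= 1)
    g <- config$gates
    stopifnot(length(g$expression_q) == 2, g$expression_q[1] >= 0,
              g$expression_q[2] <= 1, g$expression_q[1] < g$expression_q[2],
              g$target_fraction > 0, g$target_fraction <= 0.5)
    sq <- config$sequencing
    stopifnot(sq$mode %in% c("counts", "reads"), sq$reads_per_guide >= 1,
              sq$error_rate >= 0, sq$error_rate < 1, sq$n_replicates >= 1)
    ## scoringConfig() runs the scoring validity checks
    .scoringFromConfig(config)
    invisible(TRUE)
}

## internal: ScoringConfig from the nested list
.scoringFromConfig <- function(config) {
    s <- config$scoring
    scoringConfig(pseudocount = s$pseudocount, scale = s$scale,
                  window = s$window, nPerm = s$n_perm, logBase = s$log_base,
                  pThreshold = s$p_threshold,
                  phenotypeThreshold = s$phenotype_threshold,
                  seed = stageSeed(config$seed, "scoring"),
                  includeNtcInWindow = s$include_ntc_in_window,
                  includeNtcInNull = s$include_ntc_in_null,
                  ntcPseudoSize = s$ntc_pseudo_size)
}

#' Simulate a screen to on-disk artifacts
#'
#' Runs library generation, effect planting, population simulation, pulse
#' acquisition, expression and PulSA gating, replicate splitting and
#' sequencing, writing: \code{library.csv}, \code{truth_genes.tsv},
#' \code{truth_guides.tsv}, and either per-sample FASTQ files
#' (\code{sequencing$mode = "reads"}) or \code{counts.tsv} directly
#' (\code{mode = "counts"}), plus a reproducibility \code{manifest.json}
#' (configuration, seed, package version, MD5 of every artifact). All
#' randomness derives from \code{config$seed} through per-stage streams.
#'
#' @param config A validated configuration list (\code{\link{readRunConfig}}).
#' @param outDir Output directory, created if needed.
#' @return Invisible list with the in-memory objects (\code{library},
#'   \code{truth}, \code{pools}, \code{counts} or \code{fastq} paths) and
#'   \code{files}, the manifest table.
#' @export
runSimulate <- function(config, outDir) {
    validateRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sm <- config$screen_model
    lib <- generateLibrary(sm$n_genes, sm$guides_per_gene, sm$n_ntc,
                           sm$spacer_length,
                           seed = stageSeed(config$seed, "library"))
    truth <- assignEffects(
        lib, sm$n_up, sm$n_down,
        magnitudeSampler = function(n) rep(sm$effect_magnitude, n),
        efficacySampler = function(n) rep(sm$efficacy, n),
        baseLogit = stats::qlogis(sm$base_p),
        seed = stageSeed(config$seed, "effects"))
    pools <- .simulateSort(truth, config)
    files <- character()
    writeGuideLibrary(lib, file.path(outDir, "library.csv"))
    writeScreenTruth(truth, file.path(outDir, "truth"))
    files <- c("library.csv", "truth_genes.tsv", "truth_guides.tsv")

    sq <- config$sequencing
    depth <- sq$reads_per_guide * length(lib)
    sampleTallies <- .splitReplicates(pools, lib, sq$n_replicates,
                                      stageSeed(config$seed, "replicates"))
    out <- list(library = lib, truth = truth, pools = pools)
    if (sq$mode == "counts") {
        m <- vapply(names(sampleTallies), function(nm)
            sequenceCounts(sampleTallies[[nm]], depth,
                           seed = stageSeed(config$seed,
                                            paste0("seq_", nm))),
            integer(length(lib)))
        rownames(m) <- guideIds(lib)
        writeCountsTsv(m, file.path(outDir, "counts.tsv"))
        files <- c(files, "counts.tsv")
        out$counts <- .countsWithColData(m, lib)
    } else {
        design <- ampliconDesign(spacerLength = sm$spacer_length)
        fq <- character()
        for (nm in names(sampleTallies)) {
            reads <- synthesizeReads(
                sampleTallies[[nm]], lib, design, depth,
                errorRate = sq$error_rate,
                seed = stageSeed(config$seed, paste0("seq_", nm)))
            f <- paste0(nm, ".fastq")
            writeFastq(reads, file.path(outDir, f))
            fq <- c(fq, f)
        }
        files <- c(files, fq)
        out$fastq <- file.path(outDir, fq)
    }
    .writeManifest(config, outDir, files)
    out$files <- files
    invisible(out)
}

## internal: population -> sorted pools (aggregate / diffuse cell tables)
.simulateSort <- function(truth, config) {
    sm <- config$screen_model
    op <- config$optics
    nCells <- sm$cells_per_guide * length(truth@library)
    pop <- simulatePopulation(
        truth, nCells,
        guideAbundanceSpread = sm$guide_abundance_spread,
        expressionSpread = sm$expression_spread,
        meanFluorescence = sm$mean_fluorescence,
        seed = stageSeed(config$seed, "population"))
    model <- opticalModel(
        beamSigma = op$beam_sigma, cellSigmaFactor = op$cell_sigma_factor,
        punctumSigma = op$punctum_sigma,
        diameterMeanlog = op$diameter_meanlog,
        diameterSdlog = op$diameter_sdlog, scanSpeed = op$scan_speed,
        triggerThreshold = op$trigger_threshold, noiseSd = op$noise_sd)
    pd <- acquirePopulation(pop, model,
                            seed = stageSeed(config$seed, "pulse"))
    gq <- config$gates$expression_q
    gated <- gateExpression(pd, gq[1], gq[2])
    gates <- calibratePulsaGates(gated, config$gates$target_fraction)
    sorted <- applyGates(gated, gates)
    list(aggregate = sorted$aggregate@pulses,
         diffuse = sorted$diffuse@pulses,
         population = pop, gates = gates)
}

## internal: split each sorted pool into technical replicates and tally
.splitReplicates <- function(pools, lib, nReplicates, seed) {
    set.seed(seed)
    out <- list()
    for (cond in c("pos", "neg")) {
        cellsTab <- if (cond == "pos") pools$aggregate else pools$diffuse
        n <- nrow(cellsTab)
        grp <- sample(rep_len(seq_len(nReplicates), n))
        for (r in seq_len(nReplicates)) {
            nm <- sprintf("%s_rep%d", cond, r)
            out[[nm]] <- tallyGuides(cellsTab[grp == r, , drop = FALSE], lib)
        }
    }
    out
}

## internal: ScreenCounts with pos/neg + replicate colData from sample names
.countsWithColData <- function(m, lib) {
    cd <- DataFrame(
        condition = sub("_rep\\d+$", "", colnames(m)),
        replicate = as.integer(sub("^.*_rep", "", colnames(m))),
        row.names = colnames(m))
    ScreenCounts(m, lib, cd)
}

## internal: manifest with config hash and artifact checksums
.writeManifest <- function(config, outDir, files) {
    cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    cfgFile <- file.path(outDir, "config.json")
    writeLines(cfgJson, cfgFile)
    manifest <- list(
        seed = config$seed,
        config_md5 = unname(tools::md5sum(cfgFile)),
        package_version = as.character(utils::packageVersion("pulsaScreen")),
        artifacts = as.list(tools::md5sum(file.path(outDir, files))))
    names(manifest$artifacts) <- files
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}

#' Count sgRNA spacers from FASTQ samples
#'
#' @param config A validated configuration list.
#' @param fastqPaths Named character vector of FASTQ paths; names become
#'   sample ids (\code{pos_rep1} etc.). Unnamed paths use the file stem.
#' @param libraryPath Path to the library CSV/TSV.
#' @param outDir Output directory for \code{counts.tsv} and
#'   \code{counts_qc.tsv}.
#' @param maxMismatch Passed to \code{\link{countSpacers}}.
#' @return Invisible \linkS4class{ScreenCounts}.
#' @export
runCount <- function(config, fastqPaths, libraryPath, outDir,
                     maxMismatch = 0L) {
    validateRunConfig(config)
    if (!file.exists(libraryPath)) stop("library file not found: ",
                                        libraryPath)
    miss <- fastqPaths[!file.exists(fastqPaths)]
    if (length(miss)) stop("FASTQ not found: ", paste(miss, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    lib <- readGuideLibrary(libraryPath)
    design <- ampliconDesign(
        spacerLength = config$screen_model$spacer_length)
    if (is.null(names(fastqPaths)))
        names(fastqPaths) <- sub("\\.fastq(\\.gz)?$", "",
                                 basename(fastqPaths))
    res <- lapply(fastqPaths, countSpacers, library = lib, design = design,
                  maxMismatch = maxMismatch)
    m <- vapply(res, `[[`, integer(length(lib)), "counts")
    rownames(m) <- guideIds(lib)
    qc <- t(vapply(res, `[[`, integer(5), "qc"))
    writeCountsTsv(m, file.path(outDir, "counts.tsv"))
    utils::write.table(data.frame(sample = rownames(qc), qc),
                       file.path(outDir, "counts_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sc <- .countsWithColData(m, lib)
    SummarizedExperiment::colData(sc) <- cbind(
        SummarizedExperiment::colData(sc), DataFrame(qc))
    invisible(sc)
}

#' Score a screen from count and library files
#'
#' Loads the counts TSV and library, runs \code{\link{scoreScreen}} and
#' writes the result tables plus \code{volcano.tsv} (gene, phenotype,
#' \code{-log10(p)}), one row per gene.
#'
#' @param config A validated configuration list.
#' @param countsPath Path to a counts TSV with \code{pos_repN} /
#'   \code{neg_repN} sample columns.
#' @param libraryPath Path to the library CSV/TSV.
#' @param outDir Output directory.
#' @return Invisible \linkS4class{ScreenScores}.
#' @export
runScore <- function(config, countsPath, libraryPath, outDir) {
    validateRunConfig(config)
    for (p in c(countsPath, libraryPath))
        if (!file.exists(p)) stop("input not found: ", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    lib <- readGuideLibrary(libraryPath)
    counts <- readCountsTsv(countsPath, library = lib)
    counts <- .countsWithColData(
        SummarizedExperiment::assay(counts, "counts"), lib)
    scores <- scoreScreen(counts, lib, .scoringFromConfig(config))
    writeScreenScores(scores, outDir)
    g <- as.data.frame(scores@geneResults)
    utils::write.table(
        data.frame(gene = g$gene, phenotype = g$phenotype,
                   neg_log10_p = -log10(g$p_value)),
        file.path(outDir, "volcano.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(scores)
}

#' Run the full synthetic screen end to end
#'
#' \code{\link{runSimulate}}, counting (when simulating reads), scoring, and
#' an evaluation comparing called hits against the planted truth:
#' sensitivity, specificity, false discovery count, the p-value rank of each
#' planted gene, and NTC pseudo-gene hit count. Writes
#' \code{evaluation.json} alongside the stage outputs. Identical config and
#' seed reproduce identical result files.
#'
#' @param config A validated configuration list.
#' @param outDir Output directory.
#' @return Invisible list with \code{scores} (\linkS4class{ScreenScores}),
#'   \code{truth} and \code{evaluation}.
#' @export
runEndToEnd <- function(config, outDir) {
    validateRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- runSimulate(config, outDir)
    if (config$sequencing$mode == "reads") {
        fq <- sim$fastq
        names(fq) <- sub("\\.fastq(\\.gz)?$", "", basename(fq))
        counts <- runCount(config, fq, file.path(outDir, "library.csv"),
                           outDir)
    } else {
        counts <- sim$counts
    }
    scores <- runScore(config, file.path(outDir, "counts.tsv"),
                       file.path(outDir, "library.csv"), outDir)
    eval <- evaluateScreen(scores, sim$truth)
    jsonlite::write_json(eval, file.path(outDir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(scores = scores, truth = sim$truth, evaluation = eval,
                   counts = counts))
}

#' Compare screen scores against planted truth
#'
#' @param scores A \linkS4class{ScreenScores}.
#' @param truth The \linkS4class{ScreenTruth} the data were generated from.
#' @return List with \code{n_planted}, \code{n_hits},
#'   \code{true_positives}, \code{false_positives}, \code{sensitivity},
#'   \code{specificity}, \code{planted_ranks} (p-value rank of each planted
#'   gene, using the stable result ordering), \code{auroc} (of that ordering
#'   against the planted labels) and \code{ntc_pseudo_hits}.
#' @export
evaluateScreen <- function(scores, truth) {
    g <- as.data.frame(scores@geneResults)
    eff <- geneEffects(truth)
    planted <- names(eff)[eff != 0 & names(eff) != NTC_SENTINEL]
    isPlanted <- g$gene %in% planted
    pos <- seq_len(nrow(g))                  # stable order: p, |phenotype|
    tp <- sum(g$is_hit & isPlanted)
    fp <- sum(g$is_hit & !isPlanted)
    auroc <- if (any(isPlanted) && any(!isPlanted)) {
        ## P(planted ranked above null); position 1 = best
        (sum(rank(-pos)[isPlanted]) - sum(isPlanted) *
             (sum(isPlanted) + 1) / 2) / (sum(isPlanted) * sum(!isPlanted))
    } else NA_real_
    ntcHits <- if (nrow(scores@ntcResults))
        sum(scores@ntcResults$is_hit) else 0L
    list(n_planted = length(planted), n_hits = sum(g$is_hit),
         true_positives = tp, false_positives = fp,
         sensitivity = if (length(planted)) tp / length(planted) else NA,
         specificity = 1 - fp / max(sum(!isPlanted), 1),
         planted_ranks = stats::setNames(pos[isPlanted],
                                         g$gene[isPlanted]),
         auroc = auroc,
         ntc_pseudo_hits = ntcHits)
}
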