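#' Default pipeline configuration
#'
#' The pipeline runs the full analysis on either a simulated cohort
#' (default) or user-supplied files: QC, consequence classification,
#' cross-population frequency statistics, population-specific variant
#' detection, gene prioritization and the case-cohort screen under
#' nested frequency sources.
#'
#' @param simulate a [simulationConfig()] (NULL to require file inputs).
#' @param paths named list of input paths used when \code{simulate} is
#'   NULL or to override simulated inputs: focalVcf, refVcfs (named
#'   character vector), casesVcf, gff, fasta, scores, rvis, genePanel.
#' @param qc a [qcConfig()].
#' @param screen a [screenConfig()].
#' @param prioritize list(maxPercentile, minCount, madK, minDeleterious).
#' @param seed integer seed (also forwarded to the simulation).
#' @param outdir output directory for reports.
#' @return list with class "PipelineConfig".
#' @export
pipelineConfig <- function(simulate = simulationConfig(), paths = list(),
                           qc = qcConfig(), screen = screenConfig(),
                           prioritize = list(maxPercentile = 25,
                                             minCount = 2, madK = 5,
                                             minDeleterious = 3),
                           seed = 1L, outdir = tempfile("popexome_run_")) {
    if (!is.null(simulate)) simulate$seed <- as.integer(seed)
    cfg <- list(simulate = simulate, paths = paths, qc = qc,
                screen = screen, prioritize = prioritize,
                seed = as.integer(seed), outdir = outdir)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: \code{seed}, \code{outdir}, \code{simulate}
#' (scalar fields of [simulationConfig()]), \code{qc}, \code{screen},
#' \code{prioritize} and \code{paths}. Referenced paths are checked up
#' front so misconfiguration fails before any computation.
#'
#' @param path YAML file.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sim <- simulationConfig()
    if (!is.null(y$simulate)) {
        for (k in intersect(names(y$simulate),
                            c("nVariants", "seed")))
            sim[[k]] <- y$simulate[[k]]
        if (isFALSE(y$simulate$enabled)) sim <- NULL
    }
    qc <- do.call(qcConfig, y$qc %||% list())
    sc <- do.call(screenConfig, y$screen %||% list())
    pr <- utils::modifyList(list(maxPercentile = 25, minCount = 2,
                                 madK = 5, minDeleterious = 3),
                            y$prioritize %||% list())
    cfg <- pipelineConfig(simulate = sim, paths = y$paths %||% list(),
                         qc = qc, screen = sc, prioritize = pr,
                         seed = y$seed %||% 1L,
                         outdir = y$outdir %||% tempfile("popexome_run_"))
    checkPipelinePaths(cfg)
    cfg
}

checkPipelinePaths <- function(config) {
    need <- if (is.null(config$simulate))
        c("focalVcf", "casesVcf", "gff", "fasta", "scores", "rvis",
          "genePanel") else character(0)
    miss <- setdiff(need, names(config$paths))
    if (length(miss))
        stop("pipeline config: simulation disabled but input paths missing: ",
             paste(miss, collapse = ", "))
    for (nm in names(config$paths)) {
        p <- unlist(config$paths[[nm]])
        bad <- p[!file.exists(p)]
        if (length(bad))
            stop("pipeline config: input file(s) not found for '", nm,
                 "': ", paste(bad, collapse = ", "))
    }
    invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> QC -> consequence classification ->
#' population frequency statistics -> gene prioritization -> cohort
#' screens, writes every module report under \code{config$outdir}, and
#' returns (and writes) a summary with every headline statistic. The run
#' is a pure function of the configuration and seed: re-running with the
#' same YAML and seed produces a byte-identical \code{summary.json}.
#'
#' @param config a [pipelineConfig()] or a YAML path.
#' @return invisibly, the summary list; side effect: files under
#'   \code{config$outdir} including \code{summary.json}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config)) config <- readPipelineConfig(config)
    checkPipelinePaths(config)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    logmsg <- function(...) message("[popexome] ", sprintf(...))

    if (!is.null(config$simulate)) {
        logmsg("simulating cohort (seed %d)", config$seed)
        sim <- simulateCohort(config$simulate)
        emitCohortData(sim, file.path(config$outdir, "data"))
        focalLabel <- sim$config$founder$focalLabel
        panels <- sim$panels
        cases <- sim$cases
        index <- buildTranscriptIndex(sim$gff, sim$reference)
        scores <- sim$scores
        rvis <- sim$rvis
        genePanel <- sim$genePanel
    } else {
        logmsg("loading inputs")
        focal <- readCohortVcf(config$paths$focalVcf, label = "FOCAL")
        refs <- lapply(config$paths$refVcfs, readCohortVcf)
        names(refs) <- names(config$paths$refVcfs)
        panels <- c(list(FOCAL = focal), refs)
        focalLabel <- "FOCAL"
        cases <- readCohortVcf(config$paths$casesVcf, label = "CASES")
        index <- buildTranscriptIndex(config$paths$gff, config$paths$fasta)
        scores <- readScoreTable(config$paths$scores)
        rvis <- readRvisTable(config$paths$rvis)
        genePanel <- readGenePanel(config$paths$genePanel)
    }
    refLabels <- setdiff(names(panels), focalLabel)

    logmsg("QC on %d panels", length(panels))
    qcd <- lapply(panels, applyQC, config = config$qc)
    panels <- lapply(qcd, `[[`, "panel")
    writeQCReport(qcd[[focalLabel]]$qcCounts,
                  file.path(config$outdir, "qc_focal.tsv"))
    focalPanel <- panels[[focalLabel]]
    casesQC <- applyQC(cases, config$qc)$panel

    logmsg("classifying consequences for %d variants", nrow(focalPanel))
    calls <- classifyConsequences(focalPanel, index)
    writeConsequenceTable(calls, file.path(config$outdir,
                                           "consequences.tsv"))
    impacts <- summarizeImpacts(calls)

    logmsg("population frequency statistics")
    freqs <- lapply(panels, alleleCounts)
    observed <- lapply(freqs, function(fr) fr$key[fr$AC > 0L])
    focalKeys <- observed[[focalLabel]]
    overlaps <- lapply(refLabels, function(lab)
        overlapFraction(focalKeys, observed[[lab]], focalLabel, lab))
    names(overlaps) <- refLabels
    focalFreq <- freqs[[focalLabel]]
    obsIdx <- focalFreq$AC > 0L
    singletonFraction <- mean(isSingleton(focalFreq[obsIdx, ]))

    refMafs <- vapply(refLabels, function(lab) {
        m <- freqs[[lab]]$MAF[match(focalFreq$key, freqs[[lab]]$key)]
        m[is.na(m)] <- 0
        m
    }, numeric(nrow(focalFreq)))
    specific <- obsIdx & populationSpecific(focalFreq$MAF, refMafs)
    specificKeys <- focalFreq$key[specific]

    hm <- !is.na(calls$impact) & calls$impact %in% c("high", "moderate") &
        obsIdx
    mmafRef <- mmaf(focalFreq$key, freqs[refLabels])
    mmafAll <- mmaf(focalFreq$key, freqs)
    rarity <- list(
        focal = rarityDistribution(focalFreq$MAF[hm]),
        reference_mmaf = rarityDistribution(mmafRef[hm]),
        all_mmaf = rarityDistribution(mmafAll[hm]))

    logmsg("gene prioritization (%d specific variants)",
           length(specificKeys))
    delKeys <- scores$key[deleteriousFlags(scores)]
    burdens <- burdenByGene(specificKeys, calls,
                            deleteriousKeys = delKeys,
                            geneLengths = geneLengths(index), rvis = rvis)
    lenCor <- if (nrow(burdens) >= 3L &&
                  stats::sd(burdens$n_specific) > 0)
        lengthCorrelation(burdens) else NA_real_
    flt <- filterOutlierGenes(burdens, madK = config$prioritize$madK)
    prio <- rvisPrioritize(flt$burdens, config$prioritize$maxPercentile,
                           config$prioritize$minCount)
    delB <- deleteriousBurden(flt$burdens,
                              config$prioritize$minDeleterious)
    utils::write.table(burdens, file.path(config$outdir, "burdens.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    logmsg("screens")
    incidental <- screenIncidental(focalPanel, calls, genePanel,
                                   maxMaf = 0.01)
    caseCalls <- classifyConsequences(casesQC, index)
    sources <- list(reference_mmaf = freqs[refLabels],
                    all_mmaf = freqs)
    cmp <- compareFreqSources(casesQC, caseCalls, scores, sources,
                              config$screen)
    reports <- attr(cmp, "reports")
    red <- reductionStats(reports$reference_mmaf, reports$all_mmaf)
    for (nm in names(reports))
        writeScreenReport(reports[[nm]],
                          jsonPath = file.path(config$outdir,
                                               paste0("screen_", nm,
                                                      ".json")))

    summary <- list(
        seed = config$seed,
        n_variants_qc = nrow(focalPanel),
        qc_removed = as.list(qcd[[focalLabel]]$qcCounts),
        impact_counts = impacts,
        singleton_fraction = round(singletonFraction, 4),
        overlap = lapply(overlaps, function(o)
            list(reference = o$reference,
                 fraction_shared = round(o$fraction_shared, 4))),
        n_population_specific = length(specificKeys),
        specific_share_percent = round(100 * length(specificKeys) /
                                       sum(obsIdx), 1),
        rarity_high_moderate = lapply(rarity, function(r)
            as.list(round(r, 4))),
        length_correlation = if (is.na(lenCor)) NULL else round(lenCor, 3),
        outlier_genes_removed = flt$removed$gene_id,
        prioritized_genes = prio$gene_id,
        deleterious_burden_genes = delB$genes$gene_id,
        incidental_rate_percent = round(incidental$rate, 2),
        screen = list(
            sources = stats::setNames(
                lapply(names(reports), function(nm) list(
                    n_survivors = nSurvivors(reports[[nm]]),
                    n_genes = reports[[nm]]@nGenesOut,
                    removed_by_stage = as.list(removedByStage(
                        reports[[nm]])))),
                names(reports)),
            reduction_percent = red$percent_reduction,
            reduction_percent_int = red$percent_reduction_int,
            n_removed_extra = red$n_removed_extra))
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logmsg("done: %s", file.path(config$outdir, "summary.json"))
    invisible(summary)
}

#' Render a pipeline summary as a markdown report
#'
#' @param summaryJson path to a \code{summary.json} written by
#'   [runPipeline()].
#' @return character vector of markdown lines, invisibly; also printed.
#' @export
renderReport <- function(summaryJson) {
    s <- jsonlite::read_json(summaryJson)
    need <- c("n_variants_qc", "impact_counts", "overlap",
              "n_population_specific", "rarity_high_moderate", "screen")
    miss <- setdiff(need, names(s))
    if (length(miss))
        stop("summary JSON is missing required fields: ",
             paste(miss, collapse = ", "))
    pc <- function(x) sprintf("%.1f%%", 100 * as.numeric(x))
    ln <- c(
        "# Population-aware exome analysis report", "",
        sprintf("High-quality SNVs analysed: %d", s$n_variants_qc),
        sprintf("Singleton fraction: %s", pc(s$singleton_fraction)), "",
        "## Impact classes",
        sprintf("- high: %d (of which splice site: %d)",
                s$impact_counts$high, s$impact_counts$splice_site),
        sprintf("- moderate: %d", s$impact_counts$moderate),
        sprintf("- low: %d", s$impact_counts$low), "",
        "## Overlap with reference panels",
        "| reference | shared |", "|---|---|")
    for (o in s$overlap)
        ln <- c(ln, sprintf("| %s | %s |", o$reference,
                            pc(o$fraction_shared)))
    ln <- c(ln, "",
        sprintf("Population-specific variants: %d (%s%% of the panel)",
                s$n_population_specific, s$specific_share_percent), "",
        "## Rarity of high/moderate-impact variants",
        "| frequency source | very rare | rare | common |",
        "|---|---|---|---|")
    for (nm in names(s$rarity_high_moderate)) {
        r <- s$rarity_high_moderate[[nm]]
        ln <- c(ln, sprintf("| %s | %s | %s | %s |", nm, pc(r$very_rare),
                            pc(r$rare), pc(r$common)))
    }
    if (!is.null(s$incidental_rate_percent))
        ln <- c(ln, "", sprintf("Incidental-findings rate: %.2f%%",
                                as.numeric(s$incidental_rate_percent)))
    ln <- c(ln, "", "## Case screen",
        "| frequency source | survivors | genes |", "|---|---|---|")
    for (nm in names(s$screen$sources)) {
        src <- s$screen$sources[[nm]]
        ln <- c(ln, sprintf("| %s | %d | %d |", nm, src$n_survivors,
                            src$n_genes))
    }
    ln <- c(ln, "", sprintf(
        "Reduction from enlarging the frequency source: %.1f%% (%d%%)",
        as.numeric(s$screen$reduction_percent),
        as.integer(s$screen$reduction_percent_int)))
    cat(ln, sep = "\n")
    invisible(ln)
}
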