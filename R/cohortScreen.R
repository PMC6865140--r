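#' Read a gene panel (one gene per line)
#'
#' Lines starting with "#" and blank lines are ignored.
#'
#' @param path text file path.
#' @param name panel name; defaults to the file name.
#' @return list with \code{name} and \code{gene_ids} (unique, non-empty).
#' @export
readGenePanel <- function(path, name = NULL) {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    if (length(ln) == 0L) stop("gene panel '", path, "' is empty")
    list(name = name %||% sub("\\.[^.]*$", "", basename(path)),
         gene_ids = unique(ln))
}

#' Screen a cohort for incidental findings in panel genes
#'
#' Findings are high-impact variants, observed in the cohort, whose gene
#' belongs to the gene panel. The incidental-findings rate is the
#' percentage of distinct individuals carrying at least one finding
#' (dosage >= 1) among the cohort; an individual carrying several
#' findings is counted once.
#'
#' @param panel a \linkS4class{CohortPanel} (the cohort).
#' @param calls consequence table from [classifyConsequences()] for the
#'   panel's variants.
#' @param genePanel list from [readGenePanel()] (or any list with
#'   \code{gene_ids}).
#' @param maxMaf optional MAF ceiling restricting findings to rare
#'   variants (applied to the cohort's own folded MAF); NULL = no
#'   restriction.
#' @return list: \code{findings} (data.frame key, gene_id, term, AC,
#'   n_carriers), \code{n_carriers} (distinct individuals), \code{rate}
#'   (percent, full precision — round for display).
#' @examples
#' ## two singleton findings carried by two different individuals in a
#' ## cohort of 128 gives a rate of 1.5625% (printed as 1.56%)
#' @export
screenIncidental <- function(panel, calls, genePanel, maxMaf = NULL) {
    keys <- variantKeys(panel)
    hit <- calls[match(keys, calls$key), , drop = FALSE]
    d <- dosages(panel)
    carried <- rowSums(d >= 1L, na.rm = TRUE)
    fr <- alleleCounts(panel)
    sel <- !is.na(hit$impact) & hit$impact == "high" &
        hit$gene_id %in% genePanel$gene_ids & carried > 0L
    if (!is.null(maxMaf))
        sel <- sel & !is.na(fr$MAF) & fr$MAF <= maxMaf
    findings <- data.frame(key = keys[sel], gene_id = hit$gene_id[sel],
                           term = hit$term[sel], AC = fr$AC[sel],
                           n_carriers = carried[sel],
                           stringsAsFactors = FALSE, row.names = NULL)
    carriers <- if (any(sel))
        unique(unlist(lapply(which(sel), function(i)
            sampleIDs(panel)[which(!is.na(d[i, ]) & d[i, ] >= 1L)])))
    else character(0)
    list(findings = findings, n_carriers = length(carriers),
         rate = 100 * length(carriers) / ncol(panel))
}

#' Screen configuration constructor
#'
#' @param minCases minimum carrier cases, default 3.
#' @param rarityRequired required rarity class under the MMAF source,
#'   default "very_rare".
#' @param freqSource name of the MMAF panel set.
#' @param requireDeleterious apply the deleteriousness stage.
#' @return a \linkS4class{ScreenConfig}.
#' @export
screenConfig <- function(minCases = 3, rarityRequired = "very_rare",
                         freqSource = "reference", requireDeleterious = TRUE) {
    new("ScreenConfig", minCases = as.integer(minCases),
        rarityRequired = rarityRequired, freqSource = freqSource,
        requireDeleterious = requireDeleterious)
}

#' @describeIn screenConfig display method.
#' @param object a ScreenConfig.
#' @export
setMethod("show", "ScreenConfig", function(object) {
    cat(sprintf(
        "ScreenConfig: deleterious=%s, minCases=%d, rarity=%s under MMAF[%s]\n",
        object@requireDeleterious, object@minCases, object@rarityRequired,
        object@freqSource))
})

#' Case-cohort causal-variant filter cascade
#'
#' Applies, in a fixed order, (1) predicted deleterious, (2) recurrence —
#' present (dosage >= 1) in at least \code{minCases} cases, (3) rarity —
#' the variant's MMAF over the configured frequency panels falls in the
#' required rarity class (a variant absent from every panel has MMAF 0).
#' The surviving set is the intersection of the three predicates and is
#' therefore independent of stage order; the per-stage removal counts are
#' attributed in cascade order.
#'
#' @param casePanel a \linkS4class{CohortPanel} of case genotypes.
#' @param calls consequence table for the case variants (used for gene
#'   assignment of survivors; variants without calls survive with NA
#'   gene).
#' @param scores score table from [readScoreTable()]; case variants
#'   missing from the table are treated as not deleterious.
#' @param freqList named list of [alleleCounts()] data.frames, the panels
#'   combined by MMAF for the rarity stage.
#' @param config a \linkS4class{ScreenConfig}.
#' @return a \linkS4class{ScreenReport}.
#' @export
screenCases <- function(casePanel, calls, scores, freqList,
                        config = screenConfig()) {
    stopifnot(is(casePanel, "CohortPanel"), is(config, "ScreenConfig"))
    if (length(freqList) == 0L)
        stop("screen config names an empty frequency source '",
             config@freqSource, "'")
    keys <- variantKeys(casePanel)
    d <- dosages(casePanel)
    carriers <- rowSums(d >= 1L, na.rm = TRUE)
    del <- keys %in% scores$key[deleteriousFlags(scores)]
    mm <- mmaf(keys, freqList)
    rar <- as.character(rarityClass(mm)) == config@rarityRequired

    alive <- rep(TRUE, length(keys))
    removed <- integer(0)
    if (config@requireDeleterious) {
        removed["deleterious"] <- sum(alive & !del)
        alive <- alive & del
    }
    removed["recurrence"] <- sum(alive & carriers < config@minCases)
    alive <- alive & carriers >= config@minCases
    removed["rarity"] <- sum(alive & !rar)
    alive <- alive & rar

    gene <- calls$gene_id[match(keys, calls$key)]
    surv <- data.frame(key = keys[alive], gene_id = gene[alive],
                       n_cases = carriers[alive], mmaf = mm[alive],
                       stringsAsFactors = FALSE, row.names = NULL)
    new("ScreenReport", config = config,
        nVariantsIn = length(keys), nVariantsOut = sum(alive),
        nGenesOut = length(unique(surv$gene_id[!is.na(surv$gene_id)])),
        removedByStage = removed, surviving = surv)
}

#' ScreenReport accessors
#'
#' @param x a \linkS4class{ScreenReport}.
#' @return \code{nSurvivors}: surviving variant count;
#'   \code{removedByStage}: named per-stage removals; \code{surviving}:
#'   the survivor data.frame.
#' @name screenReport-accessors
NULL

#' @rdname screenReport-accessors
#' @export
setMethod("nSurvivors", "ScreenReport", function(x) x@nVariantsOut)

#' @rdname screenReport-accessors
#' @export
setMethod("removedByStage", "ScreenReport", function(x) x@removedByStage)

#' @rdname screenReport-accessors
#' @export
setMethod("surviving", "ScreenReport", function(x) x@surviving)

#' @describeIn screenReport-accessors display method.
#' @param object a ScreenReport.
#' @export
setMethod("show", "ScreenReport", function(object) {
    cat(sprintf("ScreenReport: %d -> %d variants (%d genes)\n",
                object@nVariantsIn, object@nVariantsOut, object@nGenesOut))
    for (s in names(object@removedByStage))
        cat(sprintf("  removed at %-12s %d\n", paste0(s, ":"),
                    object@removedByStage[[s]]))
})

#' Build a ScreenReport from bare counts
#'
#' Convenience constructor for comparing published before/after counts
#' with [reductionStats()] when only the counts are available.
#'
#' @param nIn,nOut variant counts before/after the cascade.
#' @param nGenesOut distinct surviving genes (default 0 = unknown).
#' @param config a \linkS4class{ScreenConfig}.
#' @return a \linkS4class{ScreenReport} with a single aggregate removal
#'   stage.
#' @export
screenReportFromCounts <- function(nIn, nOut, nGenesOut = 0L,
                                   config = screenConfig()) {
    new("ScreenReport", config = config, nVariantsIn = as.integer(nIn),
        nVariantsOut = as.integer(nOut), nGenesOut = as.integer(nGenesOut),
        removedByStage = c(cascade = as.integer(nIn) - as.integer(nOut)),
        surviving = data.frame())
}

#' Reduction achieved by enlarging the frequency source
#'
#' Compares two screens run on identical upstream inputs, where the
#' second uses a superset of frequency panels; reports how many
#' additional variants the larger source filters out, and the percent
#' reduction relative to the first screen's survivors.
#'
#' @param reportA,reportB \linkS4class{ScreenReport}s (A = smaller
#'   source).
#' @return list: n_removed_extra, percent_reduction (one decimal),
#'   percent_reduction_int (nearest integer).
#' @examples
#' a <- screenReportFromCounts(450, 157); b <- screenReportFromCounts(450, 100)
#' reductionStats(a, b)$percent_reduction_int  # 36
#' @export
reductionStats <- function(reportA, reportB) {
    outA <- nSurvivors(reportA); outB <- nSurvivors(reportB)
    if (outA == 0L)
        stop("percent reduction undefined: first screen has no survivors")
    extra <- outA - outB
    list(n_removed_extra = extra,
         percent_reduction = round(100 * extra / outA, 1),
         percent_reduction_int = as.integer(round(100 * extra / outA)))
}

#' Screen a case cohort under several frequency sources
#'
#' Runs [screenCases()] once per named panel set on identical upstream
#' inputs and tabulates survivor counts, sorted by survivor count.
#'
#' @param casePanel,calls,scores as in [screenCases()].
#' @param freqPanelSets named list; each element is itself a named list
#'   of [alleleCounts()] data.frames to combine by MMAF.
#' @param config a \linkS4class{ScreenConfig}; its \code{freqSource} is
#'   overridden per set.
#' @return data.frame (source, n_survivors, n_genes) sorted by
#'   n_survivors; the full reports in the \code{reports} attribute.
#' @export
compareFreqSources <- function(casePanel, calls, scores, freqPanelSets,
                               config = screenConfig()) {
    reports <- lapply(names(freqPanelSets), function(nm) {
        cfg <- config
        cfg@freqSource <- nm
        screenCases(casePanel, calls, scores, freqPanelSets[[nm]], cfg)
    })
    names(reports) <- names(freqPanelSets)
    tab <- data.frame(source = names(freqPanelSets),
                      n_survivors = vapply(reports, nSurvivors, integer(1)),
                      n_genes = vapply(reports, function(r) r@nGenesOut,
                                       integer(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
    tab <- tab[order(tab$n_survivors, tab$source), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "reports") <- reports
    tab
}

#' Write a ScreenReport as JSON and TSV
#'
#' @param report a \linkS4class{ScreenReport}.
#' @param jsonPath,tsvPath output paths (either may be NULL).
#' @return invisibly, a list of the written paths.
#' @export
writeScreenReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
    if (!is.null(jsonPath)) {
        obj <- list(
            config = list(minCases = report@config@minCases,
                          rarityRequired = report@config@rarityRequired,
                          freqSource = report@config@freqSource,
                          requireDeleterious = report@config@requireDeleterious),
            n_variants_in = report@nVariantsIn,
            n_variants_out = report@nVariantsOut,
            n_genes_out = report@nGenesOut,
            removed_by_stage = as.list(report@removedByStage))
        jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    }
    if (!is.null(tsvPath))
        utils::write.table(report@surviving, tsvPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(list(json = jsonPath, tsv = tsvPath))
}
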