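#' Per-gene burden of qualifying population-specific variants
#'
#' Aggregates population-specific variants into gene burdens. Each variant
#' contributes to exactly one gene — the gene of its most severe
#' consequence call — and only calls whose impact class is in
#' \code{impactFilter} are counted. Variants without a consequence call
#' are skipped and their number reported in the \code{n_skipped}
#' attribute, so that \code{sum(n_specific)} plus the skipped count equals
#' the number of input variants with a qualifying call.
#'
#' @param specificKeys character vector of population-specific variant
#'   keys.
#' @param calls consequence table from [classifyConsequences()].
#' @param impactFilter impact classes to count, default high + moderate.
#' @param deleteriousKeys optional keys flagged deleterious; counted into
#'   \code{n_deleterious}.
#' @param geneLengths optional named vector of gene lengths (bp), see
#'   [geneLengths()].
#' @param rvis optional RVIS table (gene_id, score, percentile), see
#'   [readRvisTable()].
#' @return data.frame: gene_id, n_specific, n_deleterious, gene_length,
#'   rvis_percentile; attribute \code{n_skipped} = variants without a
#'   call.
#' @export
burdenByGene <- function(specificKeys, calls,
                         impactFilter = c("high", "moderate"),
                         deleteriousKeys = character(0),
                         geneLengths = NULL, rvis = NULL) {
    hit <- calls[match(specificKeys, calls$key), , drop = FALSE]
    skipped <- sum(is.na(hit$term))
    hit <- hit[!is.na(hit$term) & hit$impact %in% impactFilter, ,
               drop = FALSE]
    genes <- sort(unique(hit$gene_id))
    n_spec <- as.integer(table(factor(hit$gene_id, levels = genes)))
    del <- hit$key %in% deleteriousKeys
    n_del <- as.integer(table(factor(hit$gene_id[del], levels = genes)))
    out <- data.frame(gene_id = genes, n_specific = n_spec,
                      n_deleterious = n_del,
                      gene_length = if (is.null(geneLengths)) NA_real_ else
                          unname(geneLengths[genes]),
                      rvis_percentile = if (is.null(rvis)) NA_real_ else
                          rvis$percentile[match(genes, rvis$gene_id)],
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "n_skipped") <- skipped
    out
}

#' Gene lengths from a transcript index
#'
#' Genomic length of a gene: span from the smallest exon start to the
#' largest exon end over all of the gene's transcripts.
#'
#' @param index a \linkS4class{TranscriptIndex}.
#' @return named numeric vector (bp) by gene_id.
#' @export
geneLengths <- function(index) {
    tx <- index@transcripts
    ex <- index@exons
    gene <- tx$gene_id[match(S4Vectors::mcols(ex)$tx_id, tx$tx_id)]
    st <- tapply(GenomicRanges::start(ex), gene, min)
    en <- tapply(GenomicRanges::end(ex), gene, max)
    out <- as.numeric(en - st + 1L)
    names(out) <- names(st)
    out
}

#' Correlation between gene burden and gene length
#'
#' Pearson product-moment correlation between the per-gene count of
#' qualifying variants and the genomic gene length. Near-zero values
#' indicate the burden signal is not a gene-size artefact.
#'
#' @param burdens data.frame from [burdenByGene()] with gene_length set.
#' @return Pearson r in [-1, 1].
#' @export
lengthCorrelation <- function(burdens) {
    ok <- !is.na(burdens$gene_length)
    x <- burdens$n_specific[ok]
    y <- burdens$gene_length[ok]
    if (length(x) < 3L)
        stop("need at least 3 genes with defined lengths")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance")
    stats::cor(x, y, method = "pearson")
}

#' Remove outlier genes from a burden table
#'
#' Default rule: a gene is an outlier when its \code{n_specific} exceeds
#' median + madK x MAD, computed over genes with nonzero burden (MAD is
#' the raw median absolute deviation, constant 1, floored at 1 because
#' integer burden counts frequently give a degenerate MAD of 0). An
#' explicit blacklist removes genes regardless of burden.
#'
#' @param burdens data.frame from [burdenByGene()].
#' @param madK multiplier for the MAD rule, default 5; NA disables the
#'   rule.
#' @param blacklist character vector of gene ids to drop unconditionally.
#' @return list: \code{burdens} (filtered) and \code{removed}
#'   (data.frame gene_id, reason).
#' @export
filterOutlierGenes <- function(burdens, madK = 5, blacklist = character(0)) {
    removed <- data.frame(gene_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
    drop <- burdens$gene_id %in% blacklist
    if (any(drop))
        removed <- rbind(removed, data.frame(
            gene_id = burdens$gene_id[drop], reason = "blacklist"))
    if (!is.na(madK)) {
        nz <- burdens$n_specific[burdens$n_specific > 0]
        if (length(nz)) {
            thr <- stats::median(nz) +
                madK * max(stats::mad(nz, constant = 1), 1)
            out <- burdens$n_specific > thr & !drop
            if (any(out))
                removed <- rbind(removed, data.frame(
                    gene_id = burdens$gene_id[out],
                    reason = sprintf("burden > %g (median + %g x MAD)",
                                     thr, madK)))
            drop <- drop | out
        }
    }
    list(burdens = burdens[!drop, , drop = FALSE], removed = removed)
}

#' Prioritize genes by intolerance score and burden
#'
#' Retains genes that are both intolerant to variation (RVIS percentile at
#' or below \code{maxPercentile}) and burdened (at least \code{minCount}
#' qualifying population-specific variants), sorted by descending burden,
#' ascending percentile, then gene id. Genes without an RVIS annotation
#' are excluded; their number is reported in the \code{n_unknown_rvis}
#' attribute.
#'
#' @param burdens data.frame from [burdenByGene()] with rvis_percentile.
#' @param maxPercentile RVIS percentile ceiling (e.g. 5 = lowest 5\%).
#' @param minCount minimum n_specific.
#' @return the prioritized subset, sorted; attribute
#'   \code{n_unknown_rvis}.
#' @export
rvisPrioritize <- function(burdens, maxPercentile, minCount) {
    unk <- is.na(burdens$rvis_percentile)
    keep <- !unk & burdens$rvis_percentile <= maxPercentile &
        burdens$n_specific >= minCount
    out <- burdens[keep, , drop = FALSE]
    out <- out[order(-out$n_specific, out$rvis_percentile, out$gene_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_unknown_rvis") <- sum(unk)
    out
}

#' Genes carrying recurrent deleterious population-specific variants
#'
#' @param burdens data.frame from [burdenByGene()] (n_deleterious set via
#'   \code{deleteriousKeys}).
#' @param minCount minimum number of deleterious specific variants,
#'   default 3.
#' @return list: \code{genes} (the qualifying subset, sorted by
#'   descending n_deleterious) and \code{histogram} (table of
#'   n_deleterious over genes with at least one).
#' @export
deleteriousBurden <- function(burdens, minCount = 3) {
    keep <- burdens$n_deleterious >= minCount
    genes <- burdens[keep, , drop = FALSE]
    genes <- genes[order(-genes$n_deleterious, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
    nz <- burdens$n_deleterious[burdens$n_deleterious > 0]
    list(genes = genes, histogram = table(nz))
}

#' Read an RVIS gene score table
#'
#' Expected TSV columns: gene (or gene_id), score, percentile. The
#' percentile convention is checked: lower scores must not have higher
#' percentiles (Spearman consistency).
#'
#' @param path TSV path.
#' @return data.frame gene_id, score, percentile.
#' @export
readRvisTable <- function(path) {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if ("gene" %in% colnames(tb) && !"gene_id" %in% colnames(tb))
        colnames(tb)[colnames(tb) == "gene"] <- "gene_id"
    stopifnot(all(c("gene_id", "score", "percentile") %in% colnames(tb)))
    if (nrow(tb) > 1L &&
        stats::cor(tb$score, tb$percentile, method = "spearman") < 0)
        warning("RVIS percentiles decrease with score; check the table")
    tb
}

#' Read a per-variant deleteriousness score table
#'
#' Expected TSV columns: chrom, pos, ref, alt, score and optionally a
#' label column ("D" = deleterious).
#'
#' @param path TSV path.
#' @return data.frame with a \code{key} column added.
#' @export
readScoreTable <- function(path) {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    tb$key <- makeVariantKey(tb$chrom, tb$pos, tb$ref, tb$alt)
    tb
}

#' Deleterious flags from a score table
#'
#' A variant is flagged deleterious when its label is "D"; when only
#' numeric scores are available, when score > cutoff (default 0.5, the
#' convention of ensemble logistic-regression predictors).
#'
#' @param scores data.frame from [readScoreTable()].
#' @param cutoff numeric score cutoff used when no label column exists.
#' @return logical vector along \code{scores} rows.
#' @export
deleteriousFlags <- function(scores, cutoff = 0.5) {
    if ("label" %in% colnames(scores))
        scores$label == "D"
    else scores$score > cutoff
}
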