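#' Read a cohort VCF into a CohortPanel
#'
#' Parses a multi-sample VCF 4.x (plain text or bgzipped) and decodes GT
#' fields into allele dosages. Records can be restricted to a target region
#' set; a record is kept iff its 1-based position falls inside one of the
#' intervals. Multiallelic records are retained as-is (ALT comma-joined)
#' for [applyQC()] to drop under its biallelic-SNV rule; their dosage is
#' the count of non-reference alleles.
#'
#' Genotypes are decoded as 0/1/2 counts of the alternate allele; any
#' genotype containing a missing allele ("." on either side, or fully
#' missing) is recorded as NA. Phased separators ("|") are accepted.
#'
#' @param path VCF file path.
#' @param region optional \linkS4class{GRanges} target region (see
#'   [readTargetBed()]); NULL keeps all records.
#' @param label cohort name; defaults to the file name without extension.
#' @return a \linkS4class{CohortPanel}.
#' @seealso [applyQC()], [writeCohortVcf()].
#' @export
readCohortVcf <- function(path, region = NULL, label = NULL) {
    if (!file.exists(path))
        stop("VCF file not found: ", path)
    vcf <- tryCatch(
        VariantAnnotation::readVcf(path, genome = "unknown"),
        error = function(e) stop("failed to parse VCF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (is.null(label))
        label <- sub("\\.vcf(\\.b?gz)?$", "", basename(path))
    gt <- VariantAnnotation::geno(vcf)
    if (!"GT" %in% names(gt)) {
        rr <- SummarizedExperiment::rowRanges(vcf)
        first <- if (length(rr)) sprintf("%s:%d",
            as.character(GenomeInfoDb::seqnames(rr))[1],
            GenomicRanges::start(rr)[1]) else "<empty>"
        stop("VCF '", path, "' has no GT genotype field (first record: ",
             first, ")")
    }
    gr <- SummarizedExperiment::rowRanges(vcf)
    keep <- rep(TRUE, length(gr))
    if (!is.null(region) && length(gr)) {
        keep <- IRanges::overlapsAny(granges(gr), region, ignore.strand = TRUE)
    }
    vcf <- vcf[keep, ]
    gr <- gr[keep]
    n <- length(gr)
    refs <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    alts <- vapply(as.list(altl), function(a)
        paste(as.character(a), collapse = ","), character(1))
    ids <- names(gr)
    # readVcf names unlabelled records "chrom:pos_REF/ALT"; treat as missing
    synth <- is.null(ids) | grepl("^.+:[0-9]+_", ids %||% character(n))
    ids <- if (is.null(ids)) rep(NA_character_, n) else
        ifelse(synth | ids %in% c(".", ""), NA_character_, ids)
    filt <- as.character(S4Vectors::mcols(gr)$FILTER)
    gtm <- VariantAnnotation::geno(vcf)$GT
    dos <- decodeGT(gtm)
    cohortPanel(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                pos = GenomicRanges::start(gr),
                ref = refs, alt = alts,
                dosage = dos, samples = colnames(gtm),
                label = label, id = ids, filter = filt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

decodeGT <- function(gtm) {
    d <- matrix(NA_integer_, nrow(gtm), ncol(gtm),
                dimnames = dimnames(gtm))
    if (!length(gtm)) return(d)
    u <- unique(as.vector(gtm))
    lut <- vapply(u, function(g) {
        al <- strsplit(g, "[/|]", perl = TRUE)[[1]]
        if (length(al) == 0L || any(al == ".") || any(al == ""))
            return(NA_integer_)
        suppressWarnings(ia <- as.integer(al))
        if (any(is.na(ia))) return(NA_integer_)
        sum(ia != 0L)
    }, integer(1))
    d[] <- lut[match(as.vector(gtm), u)]
    d
}

#' Read a BED target region
#'
#' BED intervals are 0-based half-open; they are converted to 1-based
#' closed ranges, so a BED line \code{chr1 99 100} covers exactly VCF
#' position 100. Per-chromosome intervals are normalized (sorted, merged).
#'
#' @param path BED file path.
#' @return a normalized \linkS4class{GRanges}.
#' @export
readTargetBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::reduce(GenomicRanges::sort(granges(gr)),
                          ignore.strand = TRUE)
}

#' QC configuration constructor
#'
#' @param requirePassFilter keep only FILTER == PASS or "." records.
#' @param minCallRate minimum per-site call rate in [0, 1].
#' @param biallelicSnvOnly keep only biallelic single-base SNVs.
#' @return a \linkS4class{QCConfig}.
#' @export
qcConfig <- function(requirePassFilter = TRUE, minCallRate = 0.9,
                     biallelicSnvOnly = TRUE) {
    new("QCConfig", requirePassFilter = requirePassFilter,
        minCallRate = as.numeric(minCallRate),
        biallelicSnvOnly = biallelicSnvOnly)
}

#' @describeIn qcConfig display method.
#' @param object a QCConfig.
#' @export
setMethod("show", "QCConfig", function(object) {
    cat(sprintf(
        "QCConfig: pass_filter=%s, biallelic_snv_only=%s, min_call_rate=%g\n",
        object@requirePassFilter, object@biallelicSnvOnly,
        object@minCallRate))
})

#' Apply quality filters to a cohort panel
#'
#' Filters are applied in a fixed order (FILTER status, biallelic SNV,
#' call rate); a record removed by an earlier rule is not re-counted by a
#' later one, so the per-filter removal counts sum to the total removed.
#' Record order is preserved and the operation is idempotent.
#'
#' @param panel a \linkS4class{CohortPanel}.
#' @param config a \linkS4class{QCConfig}; default [qcConfig()].
#' @return list with elements \code{panel} (the filtered
#'   \linkS4class{CohortPanel}) and \code{qcCounts} (named integer vector
#'   of removed-record counts per filter).
#' @examples
#' p <- cohortPanel(chrom = "chr1", pos = c(1, 2), ref = c("A", "C"),
#'     alt = c("G", "CT"), dosage = matrix(0L, 2, 2), label = "TOY")
#' applyQC(p)$qcCounts
#' @export
applyQC <- function(panel, config = qcConfig()) {
    stopifnot(is(panel, "CohortPanel"), is(config, "QCConfig"))
    vt <- variantTable(panel)
    alive <- rep(TRUE, nrow(vt))
    counts <- c(pass_filter = 0L, snv_only = 0L, call_rate = 0L)
    if (config@requirePassFilter) {
        ok <- vt$filter %in% c("PASS", ".") | is.na(vt$filter)
        counts["pass_filter"] <- sum(alive & !ok)
        alive <- alive & ok
    }
    if (config@biallelicSnvOnly) {
        ok <- nchar(vt$ref) == 1L & nchar(vt$alt) == 1L &
            vt$ref %in% c("A", "C", "G", "T") &
            vt$alt %in% c("A", "C", "G", "T") & vt$ref != vt$alt
        counts["snv_only"] <- sum(alive & !ok)
        alive <- alive & ok
    }
    if (config@minCallRate > 0 && ncol(panel) > 0L) {
        cr <- rowMeans(!is.na(dosages(panel)))
        ok <- cr >= config@minCallRate
        counts["call_rate"] <- sum(alive & !ok)
        alive <- alive & ok
    }
    list(panel = panel[alive, ], qcCounts = counts)
}

#' Restrict a panel to a target region
#'
#' @param panel a \linkS4class{CohortPanel}.
#' @param region a \linkS4class{GRanges} (see [readTargetBed()]).
#' @return the subset \linkS4class{CohortPanel}.
#' @export
restrictToRegion <- function(panel, region) {
    keep <- IRanges::overlapsAny(granges(rowRanges(panel)), region,
                                 ignore.strand = TRUE)
    panel[keep, ]
}

#' Write a CohortPanel as VCF
#'
#' Emits a VCF 4.x file with a GT FORMAT field; missing dosages are written
#' as "./.". Reading the file back with [readCohortVcf()] reproduces the
#' variant keys and dosage matrix (round trip).
#'
#' @param panel a \linkS4class{CohortPanel}.
#' @param path output path; ".gz" suffix triggers bgzip output.
#' @return the path, invisibly.
#' @export
writeCohortVcf <- function(panel, path) {
    vt <- variantTable(panel)
    d <- dosages(panel)
    con <- tryCatch(file(path, open = "wt"),
                    error = function(e) stop("cannot write VCF to '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        sprintf("##source=PopExome;label=%s", panelLabel(panel)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIDs(panel)), collapse = "\t")), con)
    if (nrow(vt)) {
        gtchr <- matrix("./.", nrow(d), ncol(d))
        gtchr[!is.na(d) & d == 0L] <- "0/0"
        gtchr[!is.na(d) & d == 1L] <- "0/1"
        gtchr[!is.na(d) & d == 2L] <- "1/1"
        body <- paste(vt$chrom, vt$pos,
                      ifelse(is.na(vt$id), ".", vt$id),
                      vt$ref, vt$alt, ".",
                      ifelse(is.na(vt$filter), ".", vt$filter),
                      ".", "GT",
                      apply(gtchr, 1L, paste, collapse = "\t"),
                      sep = "\t")
        if (ncol(d) == 0L)
            body <- paste(vt$chrom, vt$pos, ifelse(is.na(vt$id), ".", vt$id),
                          vt$ref, vt$alt, ".",
                          ifelse(is.na(vt$filter), ".", vt$filter),
                          ".", "GT", sep = "\t")
        writeLines(body, con)
    }
    invisible(path)
}

#' Write a QC report as TSV
#'
#' @param qcCounts named removed-count vector from [applyQC()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeQCReport <- function(qcCounts, path) {
    utils::write.table(
        data.frame(filter_name = names(qcCounts),
                   removed_count = as.integer(qcCounts)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
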