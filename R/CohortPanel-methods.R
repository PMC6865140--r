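#' Construct a CohortPanel
#'
#' Builds a \linkS4class{CohortPanel} from variant coordinates, alleles and
#' a dosage matrix. This is the low-level constructor; cohorts are normally
#' read from VCF with [readCohortVcf()] or simulated with
#' [simulateCohort()].
#'
#' @param chrom,pos character/integer vectors of chromosome and 1-based
#'   position, one element per variant.
#' @param ref,alt allele strings (uppercased internally). A biallelic SNV
#'   has single-base \code{ref} and \code{alt}; multiallelic ALT may be
#'   given comma-separated and is handled (dropped) by [applyQC()].
#' @param dosage integer matrix, variants x samples, entries in
#'   \{0, 1, 2, NA\}.
#' @param samples sample identifiers; defaults to the dosage column names.
#' @param label population/cohort name.
#' @param id optional external identifiers (e.g. rs numbers), NA where
#'   unknown.
#' @param filter optional VCF FILTER strings; defaults to "PASS".
#'
#' @return a \linkS4class{CohortPanel}.
#' @examples
#' p <- cohortPanel(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'     dosage = matrix(c(0L, 1L, 2L), 1, 3), label = "TOY")
#' variantKeys(p)
#' @export
cohortPanel <- function(chrom, pos, ref, alt, dosage, samples = NULL,
                        label = "cohort", id = NA_character_,
                        filter = "PASS") {
    n <- length(pos)
    dosage <- as.matrix(dosage)
    if (n == 0L)
        dosage <- matrix(integer(0), 0L,
                         ncol = if (is.null(samples)) 0L else length(samples))
    stopifnot(nrow(dosage) == n)
    if (is.null(samples)) samples <- colnames(dosage)
    if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(dosage)))
    dimnames(dosage) <- list(NULL, samples)
    storage.mode(dosage) <- "integer"
    gr <- GRanges(rep_len(as.character(chrom), n),
                  IRanges(start = as.integer(pos), width = 1L))
    S4Vectors::mcols(gr) <- DataFrame(
        ref = toupper(rep_len(as.character(ref), n)),
        alt = toupper(rep_len(as.character(alt), n)),
        id = rep_len(as.character(id), n),
        filter = rep_len(as.character(filter), n))
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosage),
        rowRanges = gr,
        colData = DataFrame(row.names = samples))
    new("CohortPanel", se, label = as.character(label))
}

#' Variant keys
#'
#' The canonical variant identity used across panels:
#' \code{chrom:pos:ref:alt} after uppercasing. Keys are matched exactly;
#' no allele flipping is attempted.
#'
#' @param x a \linkS4class{CohortPanel} or a data.frame with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}.
#' @param ... unused.
#' @return character vector of keys.
#' @export
setMethod("variantKeys", "CohortPanel", function(x, ...) {
    gr <- rowRanges(x)
    makeVariantKey(as.character(GenomeInfoDb::seqnames(gr)),
                   GenomicRanges::start(gr),
                   S4Vectors::mcols(gr)$ref, S4Vectors::mcols(gr)$alt)
})

#' @rdname variantKeys
#' @export
setMethod("variantKeys", "data.frame", function(x, ...) {
    makeVariantKey(x$chrom, x$pos, x$ref, x$alt)
})

makeVariantKey <- function(chrom, pos, ref, alt) {
    paste(chrom, as.integer(pos), toupper(ref), toupper(alt), sep = ":")
}

#' CohortPanel accessors
#'
#' @param x a \linkS4class{CohortPanel}.
#' @param value replacement label.
#' @return \code{panelLabel}: the cohort name; \code{dosages}: the integer
#'   dosage matrix (variants x samples); \code{sampleIDs}: sample names.
#' @name cohortPanel-accessors
NULL

#' @rdname cohortPanel-accessors
#' @export
setMethod("panelLabel", "CohortPanel", function(x) x@label)

#' @rdname cohortPanel-accessors
#' @export
setMethod("panelLabel<-", "CohortPanel", function(x, value) {
    x@label <- as.character(value)
    validObject(x)
    x
})

#' @rdname cohortPanel-accessors
#' @export
setMethod("dosages", "CohortPanel", function(x) assay(x, "dosage"))

#' @rdname cohortPanel-accessors
#' @export
setMethod("sampleIDs", "CohortPanel", function(x) colnames(x))

#' @describeIn cohortPanel-accessors compact display.
#' @param object a \linkS4class{CohortPanel}.
#' @export
setMethod("show", "CohortPanel", function(object) {
    cat(sprintf("CohortPanel '%s': %d variants x %d samples\n",
                object@label, nrow(object), ncol(object)))
    d <- dosages(object)
    nm <- sum(is.na(d))
    if (length(d))
        cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nm,
                    100 * nm / length(d)))
    if (nrow(object)) {
        k <- variantKeys(object)
        cat("  first variants:", paste(utils::head(k, 3), collapse = ", "),
            if (nrow(object) > 3) "..." else "", "\n")
    }
})

#' Variant table of a panel
#'
#' @param panel a \linkS4class{CohortPanel}.
#' @return data.frame with columns chrom, pos, ref, alt, id, filter, key.
#' @export
variantTable <- function(panel) {
    gr <- rowRanges(panel)
    mc <- S4Vectors::mcols(gr)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               pos = GenomicRanges::start(gr),
               ref = mc$ref, alt = mc$alt, id = mc$id, filter = mc$filter,
               key = variantKeys(panel),
               stringsAsFactors = FALSE, row.names = NULL)
}
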