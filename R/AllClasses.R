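#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay colData
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

#' CohortPanel: genotype dosages for one population or cohort
#'
#' A \code{CohortPanel} holds a set of variants (rows) with per-sample
#' allele dosages (columns) for a single population panel or case cohort.
#' It extends \linkS4class{RangedSummarizedExperiment}: the row ranges carry
#' the variant coordinates plus \code{ref}, \code{alt}, \code{id} and
#' \code{filter} metadata columns, and the single assay \code{"dosage"} is an
#' integer matrix with entries in \{0, 1, 2, NA\} (NA = missing genotype).
#'
#' Variant identity throughout the package is the key
#' \code{chrom:pos:ref:alt} (uppercase alleles); keys must be unique within
#' a panel.
#'
#' @slot label single string naming the population/cohort.
#'
#' @seealso [cohortPanel()] for the constructor, [readCohortVcf()],
#'   [applyQC()], [alleleCounts()].
#' @export
setClass("CohortPanel",
    contains = "RangedSummarizedExperiment",
    slots = c(label = "character"))

setValidity("CohortPanel", function(object) {
    msg <- NULL
    if (length(object@label) != 1L || is.na(object@label))
        msg <- c(msg, "'label' must be a single non-NA string")
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    mc <- S4Vectors::mcols(rowRanges(object))
    for (col in c("ref", "alt"))
        if (!col %in% colnames(mc))
            msg <- c(msg, sprintf("row ranges must carry a '%s' column", col))
    if (is.null(msg)) {
        d <- assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && (any(bad < 0) || any(bad > 2)))
            msg <- c(msg, "dosages must be in {0, 1, 2, NA}")
        k <- variantKeys(object)
        if (anyDuplicated(k))
            msg <- c(msg, "variant keys (chrom,pos,ref,alt) must be unique")
    }
    if (is.null(msg)) TRUE else msg
})

#' Quality-control configuration for a cohort panel
#'
#' Switchable filters producing the "high-quality SNV" working set. Every
#' rule can be disabled independently; the defaults keep PASS-only
#' biallelic SNVs with per-site call rate at least 0.9.
#'
#' @slot requirePassFilter keep only records whose FILTER is PASS or ".".
#' @slot minCallRate minimum fraction of samples with a called genotype,
#'   in [0, 1]; half-called genotypes count as missing. Set to 0 to disable.
#' @slot biallelicSnvOnly keep only biallelic single-nucleotide variants
#'   (single-base REF and single-base ALT); multiallelic records are
#'   dropped, not split.
#'
#' @seealso [qcConfig()], [applyQC()].
#' @export
setClass("QCConfig", slots = c(
    requirePassFilter = "logical",
    minCallRate = "numeric",
    biallelicSnvOnly = "logical"))

setValidity("QCConfig", function(object) {
    if (length(object@minCallRate) != 1L || is.na(object@minCallRate) ||
        object@minCallRate < 0 || object@minCallRate > 1)
        return("'minCallRate' must be a single value in [0, 1]")
    if (length(object@requirePassFilter) != 1L ||
        length(object@biallelicSnvOnly) != 1L)
        return("flags must be single logicals")
    TRUE
})

#' Transcript index for consequence classification
#'
#' Pre-computed lookup structure built from gene models (GFF3/GTF) and a
#' reference sequence by [buildTranscriptIndex()]. Supports point queries:
#' which coding sequences, exons and splice windows cover a genomic
#' position.
#'
#' @slot transcripts data.frame with one row per accepted transcript
#'   (tx_id, gene_id, chrom, strand, cds_len).
#' @slot cds GRanges of CDS pieces with \code{tx_id} and \code{cds_offset}
#'   (0-based offset of the piece's first base in transcript-oriented CDS
#'   coordinates).
#' @slot exons GRanges of exons with \code{tx_id}.
#' @slot spliceWindows GRanges of the two intronic bases flanking every
#'   internal exon boundary of a coding transcript, with \code{tx_id}.
#' @slot cdsSeq DNAStringSet of strand-corrected CDS sequences, one per
#'   accepted transcript (names = tx_id).
#' @slot reference DNAStringSet of reference chromosome sequences.
#' @slot rejected data.frame (tx_id, reason) of transcripts failing the
#'   model invariants.
#'
#' @export
setClass("TranscriptIndex", slots = c(
    transcripts = "data.frame",
    cds = "GRanges",
    exons = "GRanges",
    spliceWindows = "GRanges",
    cdsSeq = "DNAStringSet",
    reference = "DNAStringSet",
    rejected = "data.frame"))

#' Configuration of the case-cohort screening cascade
#'
#' Fixes the filter cascade used by [screenCases()]: (1) predicted
#' deleterious, (2) recurrent in at least \code{minCases} cases (a case
#' carries a variant iff its dosage is >= 1), (3) rarity under the maximum
#' minor allele frequency (MMAF) of the configured panel set.
#'
#' @slot minCases minimum number of carrier cases (default 3).
#' @slot rarityRequired rarity class a surviving variant must fall in under
#'   the MMAF source: "very_rare" (default), "rare" or "common".
#' @slot freqSource name of the frequency-panel set combined by MMAF.
#' @slot requireDeleterious apply the deleteriousness stage (default TRUE).
#'
#' @seealso [screenConfig()], [screenCases()], [compareFreqSources()].
#' @export
setClass("ScreenConfig", slots = c(
    minCases = "integer",
    rarityRequired = "character",
    freqSource = "character",
    requireDeleterious = "logical"))

setValidity("ScreenConfig", function(object) {
    if (length(object@minCases) != 1L || is.na(object@minCases) ||
        object@minCases < 1L)
        return("'minCases' must be a single integer >= 1")
    if (!object@rarityRequired %in% c("very_rare", "rare", "common"))
        return("'rarityRequired' must be one of very_rare, rare, common")
    TRUE
})

#' Result of a case-cohort screen
#'
#' Before/after variant and gene counts for one run of the
#' [screenCases()] filter cascade, with per-stage removal counts and the
#' surviving variants.
#'
#' @slot config the \linkS4class{ScreenConfig} used.
#' @slot nVariantsIn,nVariantsOut variant counts before/after the cascade.
#' @slot nGenesOut number of distinct genes among survivors (variants
#'   without a gene assignment are not counted).
#' @slot removedByStage named integer vector of per-stage removals, in
#'   cascade order; sums to \code{nVariantsIn - nVariantsOut}.
#' @slot surviving data.frame of surviving variants (key columns, gene,
#'   carrier count, MMAF under the configured source).
#'
#' @seealso [screenCases()], [reductionStats()].
#' @export
setClass("ScreenReport", slots = c(
    config = "ScreenConfig",
    nVariantsIn = "integer",
    nVariantsOut = "integer",
    nGenesOut = "integer",
    removedByStage = "integer",
    surviving = "data.frame"))

setValidity("ScreenReport", function(object) {
    if (object@nVariantsIn - object@nVariantsOut !=
        sum(object@removedByStage))
        return("removedByStage must sum to nVariantsIn - nVariantsOut")
    if (object@nGenesOut > object@nVariantsOut)
        return("nGenesOut cannot exceed nVariantsOut")
    TRUE
})
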