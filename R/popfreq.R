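#' Per-variant allele counts and frequencies for a panel
#'
#' Computes, for every variant, the alternate allele count (AC), the
#' number of called alleles (AN, excluding missing genotypes), the
#' alternate allele frequency AF = AC/AN and the folded minor allele
#' frequency MAF = min(AF, 1 - AF). A variant with AN = 0 carries no
#' frequency information and is flagged \code{absent} (AF/MAF are NA).
#'
#' @param panel a \linkS4class{CohortPanel}, normally after [applyQC()].
#' @return data.frame with columns chrom, pos, ref, alt, key, panel, AC,
#'   AN, AF, MAF, absent.
#' @examples
#' p <- cohortPanel("chr1", 1, "A", "G",
#'     dosage = matrix(c(0L, 1L, 1L, 2L), 1, 4), label = "TOY")
#' alleleCounts(p)[, c("AC", "AN", "AF", "MAF")]  # 4, 8, 0.5, 0.5
#' @export
alleleCounts <- function(panel) {
    stopifnot(is(panel, "CohortPanel"))
    vt <- variantTable(panel)
    d <- dosages(panel)
    AC <- as.integer(rowSums(d, na.rm = TRUE))
    AN <- as.integer(2L * rowSums(!is.na(d)))
    AF <- ifelse(AN > 0L, AC / AN, NA_real_)
    data.frame(vt[, c("chrom", "pos", "ref", "alt", "key")],
               panel = panelLabel(panel),
               AC = AC, AN = AN, AF = AF, MAF = pmin(AF, 1 - AF),
               absent = AN == 0L,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Singleton indicator
#'
#' A singleton is a variant whose alternate allele is observed exactly
#' once in the cohort (AC = 1 among called alleles).
#'
#' @param rec data.frame of frequency records (needs AC, AN), or an AC
#'   vector with \code{an} supplied.
#' @param an called allele counts when \code{rec} is a bare AC vector.
#' @return logical vector.
#' @export
isSingleton <- function(rec, an = NULL) {
    if (is.data.frame(rec)) { ac <- rec$AC; an <- rec$AN }
    else ac <- rec
    if (is.null(an)) stop("AN required")
    an > 0L & ac == 1L
}

#' Overlap of a focal variant set with a reference set
#'
#' @param focal,reference character vectors of normalized variant keys
#'   (see [variantKeys()]).
#' @param focalLabel,referenceLabel names echoed in the result.
#' @return list: n_focal, n_shared, fraction_shared, n_novel.
#' @examples
#' overlapFraction(c("a", "b", "c", "d"), c("b", "c", "d", "e"))$fraction_shared
#' @export
overlapFraction <- function(focal, reference, focalLabel = "focal",
                            referenceLabel = "reference") {
    focal <- unique(focal); reference <- unique(reference)
    if (length(focal) == 0L)
        stop("overlap fraction undefined for an empty focal set")
    ns <- sum(focal %in% reference)
    list(focal = focalLabel, reference = referenceLabel,
         n_focal = length(focal), n_shared = ns,
         fraction_shared = ns / length(focal),
         n_novel = length(focal) - ns)
}

#' Per-variant novelty flags
#'
#' A variant is novel iff its key is absent from every reference panel
#' set and from the known-identifier catalog.
#'
#' @param focal character vector of focal variant keys.
#' @param references list of character vectors (reference panel key sets).
#' @param knownIds character vector of catalogued keys (dbSNP-style).
#' @return logical vector along \code{focal}.
#' @export
noveltyFlags <- function(focal, references = list(), knownIds = character(0)) {
    seen <- rep(FALSE, length(focal))
    for (r in references) seen <- seen | focal %in% r
    seen <- seen | focal %in% knownIds
    !seen
}

#' Rarity class of a minor allele frequency
#'
#' Partition of MAF values: very_rare (MAF < veryRareMax, strictly; an
#' absent variant, NA MAF, counts as very_rare), rare (veryRareMax <= MAF
#' < rareMax) and common (MAF >= rareMax).
#'
#' @param maf numeric vector of MAFs (NA = absent).
#' @param veryRareMax very-rare threshold, default 0.01.
#' @param rareMax rare/common boundary, default 0.05 (left-closed: a MAF
#'   of exactly 0.05 is common).
#' @return factor with levels very_rare, rare, common.
#' @export
rarityClass <- function(maf, veryRareMax = 0.01, rareMax = 0.05) {
    cls <- ifelse(is.na(maf) | maf < veryRareMax, "very_rare",
           ifelse(maf < rareMax, "rare", "common"))
    factor(cls, levels = c("very_rare", "rare", "common"))
}

#' Maximum MAF (MMAF) across a set of panels
#'
#' For each requested variant key, the maximum folded MAF over all panels
#' in which the variant has frequency information (AN > 0). A variant
#' absent from every panel has MMAF 0 — absence is the strongest evidence
#' of rarity when the panels are used as a filtering resource.
#'
#' @param keys character vector of variant keys.
#' @param freqList list of frequency data.frames from [alleleCounts()]
#'   (one per panel).
#' @return numeric vector of MMAFs along \code{keys}.
#' @export
mmaf <- function(keys, freqList) {
    if (length(freqList) == 0L)
        stop("at least one frequency panel is required")
    out <- numeric(length(keys))
    for (fr in freqList) {
        m <- fr$MAF[match(keys, fr$key)]
        m[is.na(m)] <- 0
        out <- pmax(out, m)
    }
    out
}

#' Population-specific variant flag
#'
#' A variant is population specific when it is more prevalent in the focal
#' population (MAF > threshold) while very rare (MAF < threshold) or
#' absent in every reference population.
#'
#' @param focalMaf numeric vector of focal-population MAFs.
#' @param refMafs numeric matrix (variants x reference panels) or vector
#'   of reference MAFs; NA = absent, which counts as below threshold.
#' @param threshold MAF threshold, default 0.01.
#' @return logical vector.
#' @examples
#' populationSpecific(0.047, c(0.001, 0.0, 0.002))  # TRUE
#' @export
populationSpecific <- function(focalMaf, refMafs, threshold = 0.01) {
    if (is.null(dim(refMafs)))
        refMafs <- matrix(refMafs, nrow = length(focalMaf),
                          ncol = length(refMafs) / max(length(focalMaf), 1L),
                          byrow = length(focalMaf) == 1L)
    refMafs[is.na(refMafs)] <- 0
    ok_ref <- rowSums(refMafs >= threshold) == 0L
    !is.na(focalMaf) & focalMaf > threshold & ok_ref
}

#' Rarity-class distribution of a variant set
#'
#' @param maf numeric vector of MAFs (single-panel MAF or an MMAF from
#'   [mmaf()]); NA counts as very rare.
#' @param ... thresholds passed to [rarityClass()].
#' @return named numeric vector of fractions (very_rare, rare, common)
#'   summing to 1.
#' @export
rarityDistribution <- function(maf, ...) {
    if (length(maf) == 0L)
        stop("rarity distribution undefined for an empty variant set")
    tab <- table(rarityClass(maf, ...))
    as.vector(tab / sum(tab)) -> fr
    names(fr) <- names(tab)
    fr
}

#' Write panel frequency records as TSV
#'
#' @param freq data.frame from [alleleCounts()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFrequencyTable <- function(freq, path) {
    utils::write.table(
        freq[, c("chrom", "pos", "ref", "alt", "panel", "AC", "AN",
                 "AF", "MAF")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a frequency table written by [writeFrequencyTable()]
#'
#' @param path TSV path.
#' @return data.frame with a \code{key} column added.
#' @export
readFrequencyTable <- function(path) {
    fr <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    fr$key <- makeVariantKey(fr$chrom, fr$pos, fr$ref, fr$alt)
    fr$absent <- fr$AN == 0L
    fr
}
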