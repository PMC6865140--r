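#' Simulation configuration for a synthetic multi-population exome cohort
#'
#' Defines the study conditions emulated by the generator: several
#' populations diverged from a common ancestor under the Balding-Nichols
#' model, a focal population carrying a planted founder-effect variant
#' set, Hardy-Weinberg genotypes, toy coding genes on both strands with a
#' truth-labelled consequence mix, and deleteriousness scores correlated
#' with the truth labels.
#'
#' Defaults model a founder-population resequencing study: five panels of
#' 128 individuals (one focal population with stronger drift, F = 0.05,
#' and four references at F = 0.01-0.02), 1000 biallelic SNVs of which
#' 100 are planted founder variants (focal MAF uniform in 0.011-0.2,
#' essentially absent in references, MAF < 0.002), 24 coding genes (half
#' on the minus strand) hosting 524 truth-labelled consequence variants,
#' and a 49-individual case cohort drawn from the focal population's
#' allele frequencies.
#'
#' @param nVariants total number of variants.
#' @param populations data.frame(label, n, fst); the first row is the
#'   focal population unless \code{founder$focalLabel} says otherwise.
#' @param founder list(nPlanted, focalLabel, focalMafRange, refMafMax).
#' @param genes list(nGenes, exonsPerGene, cdsCodons, minusStrandFraction).
#' @param consequenceMix named integer vector of requested truth terms
#'   (stop_gained, stop_lost, splice_site, missense, synonymous,
#'   exonic_unknown); variants beyond the mix are placed intergenically.
#' @param scoreModel list(dMean, nMean, sd) for the deleterious/neutral
#'   score distributions (clipped to [0, 1]; label "D" iff score > 0.5).
#' @param cases list(label, n): case cohort sampled from the focal
#'   population's frequencies.
#' @param seed integer seed; every generator operation is a pure function
#'   of (config, seed).
#' @return a validated config (list with class "SimulationConfig").
#' @export
simulationConfig <- function(
    nVariants = 1000L,
    populations = data.frame(
        label = c("FOCAL", "EUR", "AFR", "EAS", "SAS"),
        n = rep(128L, 5),
        fst = c(0.05, 0.01, 0.02, 0.02, 0.02),
        stringsAsFactors = FALSE),
    founder = list(nPlanted = 100L, focalLabel = "FOCAL",
                   focalMafRange = c(0.011, 0.2), refMafMax = 0.002),
    genes = list(nGenes = 24L, exonsPerGene = c(2L, 5L),
                 cdsCodons = c(60L, 120L), minusStrandFraction = 0.5),
    consequenceMix = c(stop_gained = 60L, stop_lost = 24L,
                       splice_site = 60L, missense = 200L,
                       synonymous = 120L, exonic_unknown = 60L),
    scoreModel = list(dMean = 0.9, nMean = 0.1, sd = 0.05),
    cases = list(label = "CASES", n = 49L),
    seed = 1L) {
    cfg <- list(nVariants = as.integer(nVariants), populations = populations,
                founder = founder, genes = genes,
                consequenceMix = consequenceMix, scoreModel = scoreModel,
                cases = cases, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

validateSimulationConfig <- function(cfg) {
    with(cfg, {
        if (any(populations$fst <= 0 | populations$fst >= 1))
            stop("population F values must lie strictly in (0, 1)")
        if (!founder$focalLabel %in% populations$label)
            stop("founder focal label '", founder$focalLabel,
                 "' is not a population")
        if (founder$nPlanted > nVariants)
            stop("cannot plant more founder variants than variants")
        r <- founder$focalMafRange
        if (r[1] <= 0.01 || r[2] >= 0.5 || r[1] >= r[2])
            stop("focalMafRange must be an increasing range within (0.01, 0.5)")
        if (founder$refMafMax >= 0.01 || founder$refMafMax <= 0)
            stop("refMafMax must lie in (0, 0.01)")
        if (sum(consequenceMix) > nVariants)
            stop("consequence mix exceeds nVariants")
        bad <- setdiff(names(consequenceMix),
                       c("stop_gained", "stop_lost", "splice_site",
                         "missense", "synonymous", "exonic_unknown"))
        if (length(bad)) stop("unknown consequence terms: ",
                              paste(bad, collapse = ", "))
    })
    invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf(
        "SimulationConfig: %d variants, %d populations (focal %s), %d planted, %d genes, seed %d\n",
        x$nVariants, nrow(x$populations), x$founder$focalLabel,
        x$founder$nPlanted, x$genes$nGenes, x$seed))
    invisible(x)
}

.STOPS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

rTruncBeta <- function(n, a, b, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
        x <- stats::rbeta(n, a, b)
        out <- c(out, x[x > lo & x < hi])
    }
    out[seq_len(n)]
}

rBaldingNichols <- function(p, F) {
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate diverged per-population allele frequencies
#'
#' Ancestral frequencies are drawn from a U-shaped Beta(0.2, 0.2)
#' truncated to (0.001, 0.5); each population's frequency is then drawn
#' from the Balding-Nichols distribution Beta(p(1-F)/F, (1-p)(1-F)/F).
#' Planted founder variants are overwritten: focal frequency uniform in
#' \code{focalMafRange}, every reference uniform in (0, refMafMax).
#' Finally, non-planted variants that happen to satisfy the
#' population-specific criterion at the truth level are redrawn, so that
#' the planted set coincides exactly with truth-level specificity (see
#' the package vignette for the rationale).
#'
#' @param config a [simulationConfig()].
#' @param seed seed; defaults to \code{config$seed}.
#' @param founderIdx indices of planted variants; by default a seeded
#'   sample of \code{founder$nPlanted} variants.
#' @return list: \code{freq} (matrix nVariants x populations of true alt
#'   allele frequencies), \code{ancestral}, \code{founder} (logical
#'   vector).
#' @export
simulateFrequencies <- function(config, seed = config$seed,
                                founderIdx = NULL) {
    validateSimulationConfig(config)
    set.seed(seed)
    nv <- config$nVariants
    pops <- config$populations
    focal <- config$founder$focalLabel
    refLabels <- setdiff(pops$label, focal)
    p <- rTruncBeta(nv, 0.2, 0.2, 0.001, 0.5)
    freq <- vapply(seq_len(nrow(pops)), function(j)
        rBaldingNichols(p, pops$fst[j]), numeric(nv))
    colnames(freq) <- pops$label
    if (is.null(founderIdx))
        founderIdx <- sample.int(nv, config$founder$nPlanted)
    isFounder <- seq_len(nv) %in% founderIdx
    r <- config$founder$focalMafRange
    freq[founderIdx, focal] <- stats::runif(length(founderIdx), r[1], r[2])
    for (lab in refLabels)
        freq[founderIdx, lab] <- stats::runif(length(founderIdx), 0,
                                              config$founder$refMafMax)
    # redraw non-planted variants that are truth-level population specific
    maf <- function(f) pmin(f, 1 - f)
    for (iter in seq_len(200L)) {
        spec <- populationSpecific(maf(freq[, focal]),
                                   maf(freq[, refLabels, drop = FALSE]))
        bad <- which(spec & !isFounder)
        if (length(bad) == 0L) break
        p[bad] <- rTruncBeta(length(bad), 0.2, 0.2, 0.001, 0.5)
        for (j in seq_len(nrow(pops)))
            freq[bad, j] <- rBaldingNichols(p[bad], pops$fst[j])
    }
    list(freq = freq, ancestral = p, founder = isFounder)
}

#' Simulate Hardy-Weinberg genotype panels
#'
#' For each population, each individual's dosage at each variant is an
#' independent Binomial(2, f) draw at that population's true frequency.
#'
#' @param freq matrix of true frequencies (variants x populations), as
#'   from [simulateFrequencies()].
#' @param variants data.frame with chrom, pos, ref, alt (one row per
#'   frequency row).
#' @param populations data.frame(label, n).
#' @param seed integer seed.
#' @return named list of \linkS4class{CohortPanel}s.
#' @export
simulateGenotypes <- function(freq, variants, populations, seed = 1L) {
    set.seed(seed)
    nv <- nrow(freq)
    stopifnot(nrow(variants) == nv)
    panels <- lapply(seq_len(nrow(populations)), function(j) {
        lab <- populations$label[j]
        n <- populations$n[j]
        d <- matrix(stats::rbinom(nv * n, 2L, rep(freq[, lab], n)), nv, n)
        cohortPanel(variants$chrom, variants$pos, variants$ref,
                    variants$alt, d,
                    samples = sprintf("%s_%03d", lab, seq_len(n)),
                    label = lab)
    })
    names(panels) <- populations$label
    panels
}

## ---- gene model construction ----------------------------------------

randomCodingSeq <- function(ncod) {
    codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                    collapse = "")
    nonstop <- setdiff(codons, .STOPS)
    paste0("ATG",
           paste(sample(nonstop, ncod - 2L, replace = TRUE), collapse = ""),
           sample(.STOPS, 1L))
}

randomSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

revcompChar <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))

# split length L into k pieces each >= minLen
splitLengths <- function(L, k, minLen = 8L) {
    if (k == 1L) return(L)
    repeat {
        cuts <- sort(sample.int(L - 1L, k - 1L))
        len <- diff(c(0L, cuts, L))
        if (min(len) >= minLen) return(len)
    }
}

#' Simulate toy coding gene models and a reference chromosome
#'
#' Generates non-overlapping genes on one chromosome, each with a single
#' transcript whose ORF starts with ATG, contains no internal stop codon
#' and ends with exactly one stop; CDS length is divisible by 3, exons
#' may split codons, and the requested fraction of genes lies on the
#' minus strand (their genomic sequence is the reverse complement of the
#' transcript-oriented construction). First and last exons carry short
#' untranslated stretches so exonic non-CDS positions exist.
#'
#' @param config a [simulationConfig()].
#' @param seed seed; defaults to \code{config$seed}.
#' @return list: \code{gff} (GRanges of gene/mRNA/exon/CDS features,
#'   exportable as GFF3), \code{reference} (DNAStringSet, chromosome
#'   "chr1"), \code{genes} (internal per-gene layout used by
#'   [injectConsequences()]), \code{intergenic} (GRanges of spacer
#'   regions).
#' @export
simulateGeneModels <- function(config, seed = config$seed) {
    set.seed(seed)
    g <- config$genes
    chrom <- "chr1"
    spacer <- 200L
    cursor <- 0L
    genes <- list()
    segs <- character(0)
    feat <- list()
    inter <- list()
    for (i in seq_len(g$nGenes)) {
        gid <- sprintf("GENE%02d", i)
        tid <- sprintf("TX%02d", i)
        strand <- if (stats::runif(1) < g$minusStrandFraction) "-" else "+"
        ncod <- sample(g$cdsCodons[1]:g$cdsCodons[2], 1L)
        k <- sample(g$exonsPerGene[1]:g$exonsPerGene[2], 1L)
        u5 <- sample(5:20, 1L); u3 <- sample(5:20, 1L)
        cds <- randomCodingSeq(ncod)
        txseq <- paste0(randomSeq(u5), cds, randomSeq(u3))
        L <- nchar(txseq)
        exlen <- splitLengths(L, k)
        inlen <- if (k > 1L) sample(30:80, k - 1L, replace = TRUE) else
            integer(0)
        # spliced and body (pre-mRNA) intervals, transcript orientation
        sEnd <- cumsum(exlen); sStart <- sEnd - exlen + 1L
        bStart <- sStart + c(0L, cumsum(inlen))
        bEnd <- bStart + exlen - 1L
        body <- character(0)
        for (j in seq_len(k)) {
            body <- c(body, substr(txseq, sStart[j], sEnd[j]))
            if (j < k) body <- c(body, randomSeq(inlen[j]))
        }
        body <- paste(body, collapse = "")
        B <- nchar(body)
        inter[[length(inter) + 1L]] <- c(cursor + 1L, cursor + spacer)
        G1 <- cursor + spacer + 1L
        G2 <- G1 + B - 1L
        cursor <- G2
        segs <- c(segs, if (strand == "-") revcompChar(body) else body)
        b2g <- function(bp) if (strand == "-") G2 - bp + 1L else G1 + bp - 1L
        exG <- cbind(pmin(b2g(bStart), b2g(bEnd)),
                     pmax(b2g(bStart), b2g(bEnd)))
        # CDS pieces: spliced interval [u5+1, u5+3*ncod] intersected with exons
        ca <- pmax(sStart, u5 + 1L); cb <- pmin(sEnd, u5 + 3L * ncod)
        hasC <- ca <= cb
        cbS <- bStart + (ca - sStart); cbE <- bStart + (cb - sStart)
        cdG <- cbind(pmin(b2g(cbS[hasC]), b2g(cbE[hasC])),
                     pmax(b2g(cbS[hasC]), b2g(cbE[hasC])))
        genes[[gid]] <- list(gene_id = gid, tx_id = tid, chrom = chrom,
                             strand = strand, G1 = G1, G2 = G2,
                             u5 = u5, u3 = u3, ncod = ncod,
                             txseq = txseq, body = body,
                             sStart = sStart, sEnd = sEnd,
                             bStart = bStart, bEnd = bEnd)
        mk <- function(type, st, en, id = NA_character_,
                       parent = character(0), phase = NA_integer_) {
            gr <- GRanges(chrom, IRanges(st, en), strand = strand)
            gr$type <- type; gr$ID <- id
            gr$Parent <- IRanges::CharacterList(
                rep(list(parent), length(gr)))
            gr$phase <- rep_len(phase, length(gr))
            gr
        }
        cw <- cdG[, 2] - cdG[, 1] + 1L
        offs <- if (strand == "-")
            rev(cumsum(c(0L, rev(cw)))[seq_along(cw)]) else
            cumsum(c(0L, cw))[seq_along(cw)]
        feat[[length(feat) + 1L]] <- c(
            mk("gene", G1, G2, gid),
            mk("mRNA", G1, G2, tid, gid),
            mk("exon", exG[, 1], exG[, 2], parent = tid),
            mk("CDS", cdG[, 1], cdG[, 2], parent = tid,
               phase = (3L - offs %% 3L) %% 3L))
    }
    inter[[length(inter) + 1L]] <- c(cursor + 1L, cursor + spacer)
    refseq <- paste(c(rbind(vapply(seq_len(g$nGenes), function(i)
        randomSeq(spacer), character(1)), segs)), collapse = "")
    refseq <- paste0(refseq, randomSeq(spacer))
    ref <- Biostrings::DNAStringSet(refseq)
    names(ref) <- chrom
    gff <- sort(unlist(GenomicRanges::GRangesList(feat)))
    interGr <- GRanges(chrom, IRanges(
        vapply(inter, `[`, integer(1), 1L),
        vapply(inter, `[`, integer(1), 2L)))
    list(gff = gff, reference = ref, genes = genes, intergenic = interGr)
}

## map a spliced-transcript position to a body position within one gene
splicedToBody <- function(gene, sp) {
    j <- findInterval(sp, gene$sStart)
    gene$bStart[j] + (sp - gene$sStart[j])
}

bodyToGenomic <- function(gene, bp) {
    if (gene$strand == "-") gene$G2 - bp + 1L else gene$G1 + bp - 1L
}

#' Plant truth-labelled consequence variants into simulated genes
#'
#' For each requested consequence term, constructs SNVs guaranteed to
#' yield that term: coding substitutions chosen by their codon effect
#' (e.g. stop_gained sites where a single substitution creates an
#' in-frame TAA/TAG/TGA), splice-site variants at intronic offsets 1-2
#' from internal exon boundaries, and exonic_unknown variants in the
#' untranslated exon stretches. Positions are unique genome-wide; alleles
#' are reported on the plus strand.
#'
#' @param models list from [simulateGeneModels()].
#' @param consequenceMix named counts per term.
#' @param seed integer seed.
#' @return data.frame: chrom, pos, ref, alt, key, gene_id, term, impact.
#' @export
injectConsequences <- function(models, consequenceMix, seed = 1L) {
    set.seed(seed)
    code <- Biostrings::GENETIC_CODE
    cand <- lapply(models$genes, function(gene) {
        comp <- gene$strand == "-"
        flip <- function(b) if (comp) chartr("ACGT", "TGCA", b) else b
        # coding candidates: every substitution at every CDS position
        cdsSeq <- substr(gene$txseq, gene$u5 + 1L, gene$u5 + 3L * gene$ncod)
        chars <- strsplit(cdsSeq, "")[[1]]
        ci <- rep(seq_along(chars), each = 3L)
        refb <- chars[ci]
        altb <- unlist(lapply(chars, function(r) setdiff(.BASES, r)),
                       use.names = FALSE)
        cstart <- ((ci - 1L) %/% 3L) * 3L + 1L
        refcod <- substring(cdsSeq, cstart, cstart + 2L)
        altcod <- refcod
        within <- (ci - 1L) %% 3L + 1L
        substr(altcod, within, within) <- altb
        raa <- code[refcod]; aaa <- code[altcod]
        term <- ifelse(raa == aaa, "synonymous",
                ifelse(raa != "*" & aaa == "*", "stop_gained",
                ifelse(raa == "*" & aaa != "*", "stop_lost", "missense")))
        bp <- splicedToBody(gene, gene$u5 + ci)
        coding <- data.frame(chrom = gene$chrom,
                             pos = bodyToGenomic(gene, bp),
                             ref = flip(refb), alt = flip(altb),
                             gene_id = gene$gene_id, term = term,
                             stringsAsFactors = FALSE)
        # splice windows (intronic offsets 1-2 from internal boundaries)
        k <- length(gene$sStart)
        splice <- NULL
        if (k > 1L) {
            bps <- c(outer(gene$bEnd[-k], 1:2, `+`),
                     outer(gene$bStart[-1L], 1:2, `-`))
            refs <- substring(gene$body, bps, bps)
            sref <- rep(refs, each = 3L)
            salt <- unlist(lapply(refs, function(r) setdiff(.BASES, r)),
                           use.names = FALSE)
            splice <- data.frame(chrom = gene$chrom,
                                 pos = bodyToGenomic(gene, rep(bps, each = 3L)),
                                 ref = flip(sref), alt = flip(salt),
                                 gene_id = gene$gene_id, term = "splice_site",
                                 stringsAsFactors = FALSE)
        }
        # untranslated exonic positions
        L <- nchar(gene$txseq)
        utr <- c(seq_len(gene$u5), (L - gene$u3 + 1L):L)
        ubp <- splicedToBody(gene, utr)
        uref <- substring(gene$body, ubp, ubp)
        ualt <- vapply(uref, function(r) sample(setdiff(.BASES, r), 1L),
                       character(1), USE.NAMES = FALSE)
        utrdf <- data.frame(chrom = gene$chrom,
                            pos = bodyToGenomic(gene, ubp),
                            ref = flip(uref), alt = flip(ualt),
                            gene_id = gene$gene_id, term = "exonic_unknown",
                            stringsAsFactors = FALSE)
        rbind(coding, splice, utrdf)
    })
    cand <- do.call(rbind, cand)
    rownames(cand) <- NULL
    chosen <- list()
    used <- integer(0)
    for (term in names(consequenceMix)) {
        want <- consequenceMix[[term]]
        if (want == 0L) next
        pool <- cand[cand$term == term & !cand$pos %in% used, ,
                     drop = FALSE]
        pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
        pool <- pool[!duplicated(pool$pos), , drop = FALSE]
        if (nrow(pool) < want)
            stop(sprintf(
                "cannot host %d '%s' variants (only %d candidate sites); increase cdsCodons or nGenes",
                want, term, nrow(pool)))
        take <- pool[seq_len(want), , drop = FALSE]
        used <- c(used, take$pos)
        chosen[[term]] <- take
    }
    out <- do.call(rbind, chosen)
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out$key <- makeVariantKey(out$chrom, out$pos, out$ref, out$alt)
    out$impact <- impactClass(out$term)
    out[, c("chrom", "pos", "ref", "alt", "key", "gene_id", "term",
            "impact")]
}

#' Simulate deleteriousness scores correlated with truth labels
#'
#' Variants flagged deleterious in truth receive scores from
#' Normal(dMean, sd), others from Normal(nMean, sd), both clipped to
#' [0, 1]; the label is "D" iff score > 0.5.
#'
#' @param truth data.frame with chrom, pos, ref, alt and logical
#'   \code{deleterious}.
#' @param scoreModel list(dMean, nMean, sd).
#' @param seed integer seed.
#' @return data.frame: chrom, pos, ref, alt, key, score, label.
#' @export
simulateScores <- function(truth, scoreModel, seed = 1L) {
    set.seed(seed)
    n <- nrow(truth)
    mu <- ifelse(truth$deleterious, scoreModel$dMean, scoreModel$nMean)
    sc <- pmin(1, pmax(0, stats::rnorm(n, mu, scoreModel$sd)))
    data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
               alt = truth$alt,
               key = makeVariantKey(truth$chrom, truth$pos, truth$ref,
                                    truth$alt),
               score = sc, label = ifelse(sc > 0.5, "D", "T"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a complete synthetic multi-population cohort
#'
#' Orchestrates the generator: gene models and reference chromosome,
#' planted consequence variants plus intergenic filler up to
#' \code{nVariants}, diverged true frequencies with the planted founder
#' set, Hardy-Weinberg genotype panels per population, a case cohort
#' drawn from the focal population's frequencies, deleteriousness scores,
#' synthetic gene intolerance (RVIS-style) percentiles, an actionable
#' gene panel, and full truth tables.
#'
#' Truth deleteriousness is high-impact variants plus a seeded random
#' half of the missense variants.
#'
#' @param config a [simulationConfig()].
#' @return list of class "CohortSimulation": config, reference, gff,
#'   truth (per-variant truth table), truthGenes (per-gene true burdens),
#'   panels (named CohortPanel list), cases (CohortPanel), scores, rvis,
#'   genePanel, intergenic.
#' @export
simulateCohort <- function(config = simulationConfig()) {
    validateSimulationConfig(config)
    base <- config$seed
    models <- simulateGeneModels(config, seed = base)
    planted <- injectConsequences(models, config$consequenceMix,
                                  seed = base + 1L)
    nFill <- config$nVariants - nrow(planted)
    fill <- NULL
    if (nFill > 0L) {
        set.seed(base + 2L)
        refchr <- as.character(models$reference[[1]])
        pool <- unlist(lapply(seq_along(models$intergenic), function(i)
            GenomicRanges::start(models$intergenic)[i]:
                GenomicRanges::end(models$intergenic)[i]))
        pool <- setdiff(pool, planted$pos)
        pos <- sort(sample(pool, nFill))
        refb <- substring(refchr, pos, pos)
        altb <- vapply(refb, function(r) sample(setdiff(.BASES, r), 1L),
                       character(1))
        fill <- data.frame(chrom = "chr1", pos = pos, ref = refb,
                           alt = unname(altb),
                           key = makeVariantKey("chr1", pos, refb, altb),
                           gene_id = NA_character_, term = NA_character_,
                           impact = NA_character_,
                           stringsAsFactors = FALSE, row.names = NULL)
    }
    truth <- rbind(planted, fill)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL

    fr <- simulateFrequencies(config, seed = base + 3L)
    focal <- config$founder$focalLabel
    refLabels <- setdiff(config$populations$label, focal)
    freq <- fr$freq
    colnames(freq) <- paste0("freq_", colnames(freq))
    truth <- cbind(truth, freq)
    truth$founder <- fr$founder
    mafs <- pmin(fr$freq, 1 - fr$freq)
    truth$maf_focal <- mafs[, focal]
    truth$mmaf_ref <- apply(mafs[, refLabels, drop = FALSE], 1L, max)

    set.seed(base + 4L)
    delTruth <- !is.na(truth$impact) & (truth$impact == "high" |
        (truth$term == "missense" & stats::runif(nrow(truth)) < 0.5))
    truth$deleterious <- delTruth

    panels <- simulateGenotypes(fr$freq, truth, config$populations,
                                seed = base + 5L)
    casePop <- data.frame(label = config$cases$label, n = config$cases$n,
                          stringsAsFactors = FALSE)
    caseFreq <- fr$freq[, focal, drop = FALSE]
    colnames(caseFreq) <- config$cases$label
    cases <- simulateGenotypes(caseFreq, truth, casePop,
                               seed = base + 6L)[[1]]

    scores <- simulateScores(truth, config$scoreModel, seed = base + 7L)

    set.seed(base + 8L)
    gids <- unname(vapply(models$genes, `[[`, character(1), "gene_id"))
    rscore <- stats::rnorm(length(gids))
    rvis <- data.frame(gene_id = gids, score = rscore,
                       percentile = 100 * (rank(rscore) - 1) /
                           (length(rscore) - 1),
                       stringsAsFactors = FALSE, row.names = NULL)
    genePanel <- list(name = "actionable_syn",
                      gene_ids = sort(sample(gids,
                                             max(2L, length(gids) %/% 4L))))

    # per-gene true burdens of founder-specific variants
    qual <- truth$founder & !is.na(truth$impact) &
        truth$impact %in% c("high", "moderate")
    tg <- data.frame(gene_id = gids, stringsAsFactors = FALSE)
    tg$n_specific <- unname(vapply(gids, function(g)
        sum(qual & truth$gene_id == g, na.rm = TRUE), integer(1)))
    tg$n_deleterious <- unname(vapply(gids, function(g)
        sum(qual & truth$deleterious & truth$gene_id == g, na.rm = TRUE),
        integer(1)))
    out <- list(config = config, reference = models$reference,
                gff = models$gff, genes = models$genes,
                intergenic = models$intergenic,
                truth = truth, truthGenes = tg, panels = panels,
                cases = cases, scores = scores, rvis = rvis,
                genePanel = genePanel)
    class(out) <- "CohortSimulation"
    out
}

#' @export
print.CohortSimulation <- function(x, ...) {
    cat(sprintf(
        "CohortSimulation: %d variants (%d planted founder, %d coding), %d panels + %d cases, seed %d\n",
        nrow(x$truth), sum(x$truth$founder), sum(!is.na(x$truth$term)),
        length(x$panels), ncol(x$cases), x$config$seed))
    invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF per population (and the case cohort), the gene models as
#' GFF3, the reference as FASTA, per-panel frequency TSVs, the score and
#' RVIS tables, the gene panel list, the truth tables and the
#' configuration as YAML — all re-readable by their consuming functions.
#'
#' @param sim a [simulateCohort()] result.
#' @param outdir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
emitCohortData <- function(sim, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (lab in names(sim$panels)) {
        p <- file.path(outdir, paste0(lab, ".vcf"))
        writeCohortVcf(sim$panels[[lab]], p)
        paths[[paste0("vcf_", lab)]] <- p
        f <- file.path(outdir, paste0("freq_", lab, ".tsv"))
        writeFrequencyTable(alleleCounts(sim$panels[[lab]]), f)
        paths[[paste0("freq_", lab)]] <- f
    }
    paths$vcf_cases <- file.path(outdir, "cases.vcf")
    writeCohortVcf(sim$cases, paths$vcf_cases)
    paths$gff <- file.path(outdir, "genes.gff3")
    rtracklayer::export(sim$gff, paths$gff, format = "gff3")
    paths$fasta <- file.path(outdir, "reference.fa")
    Biostrings::writeXStringSet(sim$reference, paths$fasta)
    paths$scores <- file.path(outdir, "scores.tsv")
    utils::write.table(sim$scores[, c("chrom", "pos", "ref", "alt",
                                      "score", "label")],
                       paths$scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$rvis <- file.path(outdir, "rvis.tsv")
    utils::write.table(sim$rvis, paths$rvis, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$genePanel <- file.path(outdir, "gene_panel.txt")
    writeLines(sim$genePanel$gene_ids, paths$genePanel)
    paths$truth <- file.path(outdir, "truth_variants.tsv")
    utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truthGenes <- file.path(outdir, "truth_genes.tsv")
    utils::write.table(sim$truthGenes, paths$truthGenes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$config <- file.path(outdir, "config.yaml")
    cfg <- sim$config
    cfg$populations <- as.list(cfg$populations)
    yaml::write_yaml(unclass(cfg), paths$config)
    invisible(paths)
}
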