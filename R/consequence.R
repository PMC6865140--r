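#' Build a transcript index from gene models and reference sequence
#'
#' Parses GFF3 gene models (gene / mRNA|transcript / exon / CDS features
#' with ID/Parent attributes) and a reference FASTA, validates every
#' transcript against the model invariants, and pre-computes the lookup
#' structures used by [classifyConsequences()]: CDS pieces with
#' transcript-oriented offsets, strand-corrected CDS sequences, exon
#' ranges, and the 2-bp intronic splice windows flanking every internal
#' exon boundary.
#'
#' Transcripts violating any invariant (overlapping or unsorted exons, CDS
#' outside exons, CDS length not divisible by 3, chromosome missing from
#' the FASTA or interval outside it) are rejected with a named reason and
#' reported in the \code{rejected} slot; an error is raised only if no
#' transcript survives.
#'
#' @param gff GFF3 path, or a \linkS4class{GRanges} as returned by
#'   \code{rtracklayer::import}.
#' @param fasta FASTA path, or a named \linkS4class{DNAStringSet}.
#' @return a \linkS4class{TranscriptIndex}.
#' @export
buildTranscriptIndex <- function(gff, fasta) {
    g <- if (is(gff, "GRanges")) gff else
        rtracklayer::import(gff, format = "gff3")
    ref <- if (is(fasta, "DNAStringSet")) fasta else
        Biostrings::readDNAStringSet(fasta)
    names(ref) <- sub("\\s.*$", "", names(ref))
    typ <- tolower(as.character(g$type))
    istx <- typ %in% c("mrna", "transcript")
    txs <- g[istx]
    if (length(txs) == 0L)
        stop("no mRNA/transcript features in gene models")
    txid <- as.character(txs$ID)
    gene_of <- as.character(unlist(txs$Parent))
    if (length(gene_of) != length(txid))
        gene_of <- vapply(txs$Parent, function(p)
            if (length(p)) as.character(p)[1] else NA_character_, character(1))
    kids <- g[typ %in% c("exon", "cds")]
    kidparent <- vapply(kids$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1))

    txdf <- data.frame(tx_id = character(0), gene_id = character(0),
                       chrom = character(0), strand = character(0),
                       cds_len = integer(0), stringsAsFactors = FALSE)
    rejected <- data.frame(tx_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
    cdsL <- list(); exonL <- list(); spliceL <- list(); seqL <- list()

    for (i in seq_along(txid)) {
        tid <- txid[i]
        mine <- kids[kidparent == tid]
        ex <- mine[tolower(as.character(mine$type)) == "exon"]
        cd <- mine[tolower(as.character(mine$type)) == "cds"]
        chrom <- as.character(GenomeInfoDb::seqnames(txs))[i]
        strand <- as.character(BiocGenerics::strand(txs))[i]
        reject <- function(why) {
            rejected[nrow(rejected) + 1L, ] <<- list(tid, why)
        }
        if (!chrom %in% names(ref)) { reject("missing_chromosome"); next }
        if (length(ex) == 0L) { reject("no_exons"); next }
        ex <- GenomicRanges::sort(granges(ex), ignore.strand = TRUE)
        cd <- GenomicRanges::sort(granges(cd), ignore.strand = TRUE)
        if (length(GenomicRanges::reduce(ex)) != length(ex)) {
            reject("overlapping_exons"); next
        }
        if (max(GenomicRanges::end(ex)) > Biostrings::width(ref[chrom])) {
            reject("outside_reference"); next
        }
        if (length(cd)) {
            inex <- IRanges::overlapsAny(cd, ex, type = "within",
                                         ignore.strand = TRUE)
            if (!all(inex)) { reject("cds_outside_exons"); next }
            clen <- sum(GenomicRanges::width(cd))
            if (clen %% 3L != 0L) { reject("cds_length_not_multiple_of_3"); next }
        } else { reject("no_cds"); next }

        # transcript-oriented CDS pieces: 5'->3'
        ord <- if (strand == "-") rev(seq_along(cd)) else seq_along(cd)
        cdo <- cd[ord]
        w <- GenomicRanges::width(cdo)
        offs <- cumsum(c(0L, w))[seq_along(w)]
        pieces <- granges(cdo)
        S4Vectors::mcols(pieces) <- DataFrame(tx_id = tid, cds_offset = offs)
        cdsL[[tid]] <- pieces
        exg <- granges(ex)
        S4Vectors::mcols(exg) <- DataFrame(tx_id = tid)
        exonL[[tid]] <- exg
        # CDS sequence, strand-corrected
        segs <- lapply(seq_along(cdo), function(j)
            Biostrings::subseq(ref[[chrom]],
                               GenomicRanges::start(cdo)[j],
                               GenomicRanges::end(cdo)[j]))
        seq5 <- do.call(Biostrings::xscat, segs)
        if (strand == "-") seq5 <- Biostrings::reverseComplement(
            do.call(Biostrings::xscat, rev(segs)))
        seqL[[tid]] <- seq5
        # splice windows: 2 intronic bases flanking internal boundaries
        if (length(ex) > 1L) {
            ends <- GenomicRanges::end(ex)[-length(ex)]
            starts <- GenomicRanges::start(ex)[-1L]
            win <- c(GRanges(chrom, IRanges(ends + 1L, ends + 2L)),
                     GRanges(chrom, IRanges(starts - 2L, starts - 1L)))
            S4Vectors::mcols(win) <- DataFrame(tx_id = tid)
            spliceL[[tid]] <- win
        }
        txdf[nrow(txdf) + 1L, ] <- list(tid, gene_of[i], chrom, strand,
                                        sum(GenomicRanges::width(cd)))
    }
    if (nrow(txdf) == 0L)
        stop("all transcripts rejected: ",
             paste(unique(rejected$reason), collapse = ", "))
    cds <- if (length(cdsL)) unlist(GenomicRanges::GRangesList(cdsL),
                                    use.names = FALSE) else GRanges()
    exons <- unlist(GenomicRanges::GRangesList(exonL), use.names = FALSE)
    splice <- if (length(spliceL)) unlist(GenomicRanges::GRangesList(spliceL),
                                          use.names = FALSE) else GRanges()
    new("TranscriptIndex", transcripts = txdf, cds = cds, exons = exons,
        spliceWindows = splice,
        cdsSeq = Biostrings::DNAStringSet(seqL),
        reference = ref, rejected = rejected)
}

#' @describeIn buildTranscriptIndex display method.
#' @param object a TranscriptIndex.
#' @export
setMethod("show", "TranscriptIndex", function(object) {
    cat(sprintf(
        "TranscriptIndex: %d transcripts (%d genes) on %d sequence(s); %d rejected\n",
        nrow(object@transcripts), length(unique(object@transcripts$gene_id)),
        length(object@reference), nrow(object@rejected)))
})

.SEVERITY <- c(stop_gained = 4L, stop_lost = 4L, splice_site = 4L,
               missense = 3L, synonymous = 2L, exonic_unknown = 1L)

#' Impact class of a consequence term
#'
#' Three-level severity scheme: high (stop_gained, stop_lost, splice_site),
#' moderate (missense), low (synonymous, exonic_unknown).
#'
#' @param term character vector of consequence terms.
#' @return character vector in \{"high", "moderate", "low"\}.
#' @export
impactClass <- function(term) {
    out <- rep(NA_character_, length(term))
    out[term %in% c("stop_gained", "stop_lost", "splice_site")] <- "high"
    out[term == "missense"] <- "moderate"
    out[term %in% c("synonymous", "exonic_unknown")] <- "low"
    out
}

#' Classify SNV consequences against a transcript index
#'
#' For each biallelic SNV, finds all overlapping transcripts and reports
#' the most severe consequence (severity: stop_gained = stop_lost =
#' splice_site > missense > synonymous > exonic_unknown; ties across
#' transcripts broken by lexicographically smallest transcript id).
#' Codon effects are computed by substituting the (strand-corrected) alt
#' base into the transcript's CDS and translating the affected codon with
#' the standard genetic code. A position in the 2-bp intronic window
#' flanking an internal exon boundary of a coding transcript is
#' splice_site; an exonic position outside the CDS is exonic_unknown;
#' positions overlapping nothing yield no call (NA term).
#'
#' A variant whose REF base disagrees with the reference sequence at a CDS
#' position raises an error (this catches coordinate bugs).
#'
#' @param variants a \linkS4class{CohortPanel} or data.frame with columns
#'   chrom, pos, ref, alt (biallelic SNVs).
#' @param index a \linkS4class{TranscriptIndex}.
#' @return data.frame with one row per input variant: chrom, pos, ref,
#'   alt, key, gene_id, tx_id, term, impact (NA for uncalled variants).
#' @examples
#' ## see the package vignette for a worked toy gene
#' @export
classifyConsequences <- function(variants, index) {
    v <- if (is(variants, "CohortPanel")) variantTable(variants) else variants
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% colnames(v)))
    n <- nrow(v)
    out <- data.frame(chrom = as.character(v$chrom), pos = as.integer(v$pos),
                      ref = toupper(v$ref), alt = toupper(v$alt),
                      key = makeVariantKey(v$chrom, v$pos, v$ref, v$alt),
                      gene_id = NA_character_, tx_id = NA_character_,
                      term = NA_character_, impact = NA_character_,
                      stringsAsFactors = FALSE, row.names = NULL)
    if (n == 0L) return(out)
    snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
        out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T")
    vg <- GRanges(out$chrom, IRanges(out$pos, width = 1L))
    txdf <- index@transcripts
    code <- Biostrings::GENETIC_CODE

    gather <- function(hits, term_fn) {
        # hits: data.frame(vi, tx_id, term)
        hits
    }
    hits <- list()
    # splice windows
    if (length(index@spliceWindows)) {
        ov <- GenomicRanges::findOverlaps(vg, index@spliceWindows,
                                          ignore.strand = TRUE)
        if (length(ov)) {
            qi <- S4Vectors::queryHits(ov)
            keep <- snv[qi]
            hits[[length(hits) + 1L]] <- data.frame(
                vi = qi[keep],
                tx_id = S4Vectors::mcols(index@spliceWindows)$tx_id[
                    S4Vectors::subjectHits(ov)][keep],
                term = "splice_site", stringsAsFactors = FALSE)
        }
    }
    # CDS hits
    ov <- GenomicRanges::findOverlaps(vg, index@cds, ignore.strand = TRUE)
    if (length(ov)) {
        qi <- S4Vectors::queryHits(ov)
        si <- S4Vectors::subjectHits(ov)
        keep <- snv[qi]
        qi <- qi[keep]; si <- si[keep]
        if (length(qi)) {
            piece <- index@cds[si]
            tid <- S4Vectors::mcols(piece)$tx_id
            str <- txdf$strand[match(tid, txdf$tx_id)]
            # transcript-oriented 0-based CDS index
            idx <- ifelse(str == "-",
                S4Vectors::mcols(piece)$cds_offset +
                    (GenomicRanges::end(piece) - out$pos[qi]),
                S4Vectors::mcols(piece)$cds_offset +
                    (out$pos[qi] - GenomicRanges::start(piece)))
            terms <- character(length(qi))
            for (j in seq_along(qi)) {
                cseq <- index@cdsSeq[[tid[j]]]
                refb <- out$ref[qi[j]]; altb <- out$alt[qi[j]]
                if (str[j] == "-") {
                    refb <- chartr("ACGT", "TGCA", refb)
                    altb <- chartr("ACGT", "TGCA", altb)
                }
                have <- as.character(Biostrings::subseq(cseq, idx[j] + 1L,
                                                        idx[j] + 1L))
                if (have != refb)
                    stop(sprintf(
                        "reference mismatch at %s:%d (VCF ref %s, reference sequence %s)",
                        out$chrom[qi[j]], out$pos[qi[j]], out$ref[qi[j]],
                        if (str[j] == "-") chartr("ACGT", "TGCA", have) else have))
                cstart <- (idx[j] %/% 3L) * 3L + 1L
                refcod <- as.character(Biostrings::subseq(cseq, cstart,
                                                          cstart + 2L))
                altcod <- refcod
                substr(altcod, idx[j] %% 3L + 1L, idx[j] %% 3L + 1L) <- altb
                raa <- code[[refcod]]; aaa <- code[[altcod]]
                terms[j] <- if (raa == aaa) "synonymous"
                    else if (raa != "*" && aaa == "*") "stop_gained"
                    else if (raa == "*" && aaa != "*") "stop_lost"
                    else "missense"
            }
            hits[[length(hits) + 1L]] <- data.frame(
                vi = qi, tx_id = tid, term = terms, stringsAsFactors = FALSE)
        }
    }
    # exon (non-CDS) hits -> exonic_unknown
    ov <- GenomicRanges::findOverlaps(vg, index@exons, ignore.strand = TRUE)
    if (length(ov)) {
        qi <- S4Vectors::queryHits(ov)
        keep <- snv[qi]
        hits[[length(hits) + 1L]] <- data.frame(
            vi = qi[keep],
            tx_id = S4Vectors::mcols(index@exons)$tx_id[
                S4Vectors::subjectHits(ov)][keep],
            term = "exonic_unknown", stringsAsFactors = FALSE)
    }
    if (length(hits)) {
        h <- do.call(rbind, hits)
        # within one (variant, transcript): keep the most severe term
        h <- h[order(h$vi, -.SEVERITY[h$term], h$tx_id), , drop = FALSE]
        h <- h[!duplicated(paste(h$vi, h$tx_id)), , drop = FALSE]
        # across transcripts: most severe, tie -> smallest tx_id (already sorted)
        h <- h[!duplicated(h$vi), , drop = FALSE]
        out$term[h$vi] <- h$term
        out$tx_id[h$vi] <- h$tx_id
        out$gene_id[h$vi] <- txdf$gene_id[match(h$tx_id, txdf$tx_id)]
        out$impact <- impactClass(out$term)
    }
    out
}

#' Classify a single variant
#'
#' Convenience wrapper over [classifyConsequences()] for one variant.
#'
#' @param chrom,pos,ref,alt the variant (biallelic SNV).
#' @param index a \linkS4class{TranscriptIndex}.
#' @return a one-row data.frame, or NULL if no transcript or splice window
#'   overlaps the position.
#' @export
classifyConsequence <- function(chrom, pos, ref, alt, index) {
    r <- classifyConsequences(
        data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt), index)
    if (is.na(r$term[1])) NULL else r
}

#' Summarize impact classes
#'
#' @param calls data.frame from [classifyConsequences()]; uncalled rows
#'   (NA term) are ignored.
#' @return named list: counts per impact class (high, moderate, low), the
#'   splice-site subcount within high, and the total number of calls.
#' @export
summarizeImpacts <- function(calls) {
    t0 <- calls$term[!is.na(calls$term)]
    imp <- impactClass(t0)
    list(high = sum(imp == "high"),
         splice_site = sum(t0 == "splice_site"),
         moderate = sum(imp == "moderate"),
         low = sum(imp == "low"),
         n = length(t0))
}

#' Write a consequence table as TSV
#'
#' @param calls data.frame from [classifyConsequences()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeConsequenceTable <- function(calls, path) {
    utils::write.table(
        calls[, c("chrom", "pos", "ref", "alt", "gene_id", "term", "impact")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
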