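# Brute-force consequence oracle, independent of the package's
# TranscriptIndex: classifies an SNV by rebuilding the ENTIRE mutated
# protein of every overlapping transcript and diffing it against the
# reference protein. Splice-site and exonic-unknown calls are positional.

oracleIndex <- function(gff) {
    typ <- tolower(as.character(gff$type))
    txs <- gff[typ %in% c("mrna", "transcript")]
    kids <- gff[typ %in% c("exon", "cds")]
    kidpar <- vapply(kids$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1))
    lapply(seq_along(txs), function(i) {
        tid <- as.character(txs$ID[i])
        mine <- kids[!is.na(kidpar) & kidpar == tid]
        mtyp <- tolower(as.character(mine$type))
        ex <- mine[mtyp == "exon"]
        cd <- mine[mtyp == "cds"]
        o <- order(GenomicRanges::start(ex))
        exs <- GenomicRanges::start(ex)[o]; exe <- GenomicRanges::end(ex)[o]
        o <- order(GenomicRanges::start(cd))
        list(tx_id = tid,
             chrom = as.character(GenomeInfoDb::seqnames(txs))[i],
             strand = as.character(BiocGenerics::strand(txs))[i],
             exs = exs, exe = exe,
             cds = cbind(GenomicRanges::start(cd)[o],
                         GenomicRanges::end(cd)[o]))
    })
}

oracleProtein <- function(chromStr, tx) {
    pieces <- vapply(seq_len(nrow(tx$cds)), function(j)
        substr(chromStr, tx$cds[j, 1], tx$cds[j, 2]), character(1))
    cds <- paste(pieces, collapse = "")
    if (tx$strand == "-")
        cds <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cds)))
    # no.init.codon: use the plain codon table so that a damaged start
    # codon shows up as a residue change, not as an alternative initiator
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       no.init.codon = TRUE))
}

oracleTermOne <- function(chrom, pos, ref, alt, oidx, refSeqs) {
    sev <- c(stop_gained = 4, stop_lost = 4, splice_site = 4,
             missense = 3, synonymous = 2, exonic_unknown = 1)
    chromStr <- as.character(refSeqs[[chrom]])
    stopifnot(substr(chromStr, pos, pos) == ref)
    mut <- chromStr
    substr(mut, pos, pos) <- alt
    best <- NA_character_
    for (tx in oidx) {
        if (tx$chrom != chrom) next
        term <- NA_character_
        k <- length(tx$exs)
        inSplice <- FALSE
        if (k > 1L) {
            don <- c(outer(tx$exe[-k], 1:2, `+`))
            acc <- c(outer(tx$exs[-1L], 1:2, `-`))
            inSplice <- pos %in% c(don, acc)
        }
        inCds <- any(pos >= tx$cds[, 1] & pos <= tx$cds[, 2])
        inExon <- any(pos >= tx$exs & pos <= tx$exe)
        if (inSplice) {
            term <- "splice_site"
        } else if (inCds) {
            pr <- strsplit(oracleProtein(chromStr, tx), "")[[1]]
            pa <- strsplit(oracleProtein(mut, tx), "")[[1]]
            n <- length(pr)
            term <- if (identical(pr, pa)) "synonymous"
                else if (pr[n] == "*" && pa[n] != "*" &&
                         !any(pa == "*" & pr != "*")) "stop_lost"
                else if (any(pa == "*" & pr != "*")) "stop_gained"
                else if (sum(pr != pa) == 1L) "missense"
                else stop("oracle: unexpected multi-residue change")
        } else if (inExon) {
            term <- "exonic_unknown"
        }
        if (!is.na(term) &&
            (is.na(best) || sev[term] > sev[best] ||
             (sev[term] == sev[best] && FALSE)))
            best <- term
    }
    best
}

oracleTerms <- function(variants, gff, refSeqs) {
    oidx <- oracleIndex(gff)
    vapply(seq_len(nrow(variants)), function(i)
        oracleTermOne(variants$chrom[i], variants$pos[i], variants$ref[i],
                      variants$alt[i], oidx, refSeqs), character(1))
}
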