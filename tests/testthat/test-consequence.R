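test_that("transcript index validates gene models and rejects bad ones", {
    toy <- toyPlusGene()
    idx <- buildTranscriptIndex(toy$gff, toy$ref)
    expect_equal(nrow(idx@transcripts), 1L)
    expect_equal(idx@transcripts$gene_id, "G1")
    expect_equal(as.character(idx@cdsSeq[["T1"]]), "ATGTACCTGTAA")
    expect_equal(nrow(idx@rejected), 0L)
    # splice windows: 2 intronic bases each side of the internal boundary
    sw <- sort(GenomicRanges::start(idx@spliceWindows))
    expect_equal(sw, c(24L, 52L))
    expect_equal(sort(GenomicRanges::end(idx@spliceWindows)), c(25L, 53L))

    # CDS length 10 (not divisible by 3) -> rejected with named reason
    bad <- toy$gff
    cdsrows <- which(tolower(as.character(bad$type)) == "cds")
    GenomicRanges::end(bad)[cdsrows[2]] <- 55L  # CDS pieces now 8 + 2
    expect_error(buildTranscriptIndex(bad, toy$ref),
                 "cds_length_not_multiple_of_3")

    # missing chromosome in the FASTA
    wrongref <- toy$ref
    names(wrongref) <- "chrZ"
    expect_error(buildTranscriptIndex(toy$gff, wrongref), "rejected")
})

test_that("codon-level classification matches hand translation", {
    toy <- toyPlusGene()
    idx <- buildTranscriptIndex(toy$gff, toy$ref)
    cls <- function(pos, ref, alt)
        classifyConsequence("chrT", pos, ref, alt, idx)
    # TAC -> TAA (Tyr -> stop) at codon position 3
    r <- cls(21, "C", "A")
    expect_equal(r$term, "stop_gained"); expect_equal(r$impact, "high")
    # CTG -> CTA (both Leu), codon spanning the splice junction
    r <- cls(54, "G", "A")
    expect_equal(r$term, "synonymous"); expect_equal(r$impact, "low")
    # terminal TAA -> TCA removes the stop
    r <- cls(56, "A", "C")
    expect_equal(r$term, "stop_lost"); expect_equal(r$impact, "high")
    # TAA -> TGA is still a stop: synonymous
    expect_equal(cls(56, "A", "G")$term, "synonymous")
    # ATG -> AAG disrupts the start codon: classified missense (moderate)
    r <- cls(17, "T", "A")
    expect_equal(r$term, "missense"); expect_equal(r$impact, "moderate")
    # first intronic base past the exon end
    r <- cls(24, "G", "C")
    expect_equal(r$term, "splice_site"); expect_equal(r$impact, "high")
    # 2 bp into the intron on the acceptor side
    expect_equal(cls(52, "T", "A")$term, "splice_site")
    # 3 bp in is not a splice site, and intron interior gives no call
    expect_null(cls(26, "T", "A"))
    # UTR exon position
    r <- cls(12, "G", "T")
    expect_equal(r$term, "exonic_unknown"); expect_equal(r$impact, "low")
    # outside any gene
    expect_null(cls(3, "A", "G"))
    # ref mismatch is an error, not a silent skip
    expect_error(cls(21, "G", "A"), "mismatch")
})

test_that("a minus-strand mirror gene yields identical terms", {
    toy <- toyPlusGene()
    mir <- toyMinusGene()
    idxP <- buildTranscriptIndex(toy$gff, toy$ref)
    idxM <- buildTranscriptIndex(mir$gff, mir$ref)
    expect_equal(as.character(idxM@cdsSeq[["T1"]]), "ATGTACCTGTAA")
    cases <- data.frame(pos = c(21, 54, 56, 17, 24, 12),
                        ref = c("C", "G", "A", "T", "G", "G"),
                        alt = c("A", "A", "C", "A", "C", "T"))
    for (i in seq_len(nrow(cases))) {
        p <- classifyConsequence("chrT", cases$pos[i], cases$ref[i],
                                 cases$alt[i], idxP)
        m <- classifyConsequence("chrT", mir$mirror(cases$pos[i]),
                                 mir$comp(cases$ref[i]),
                                 mir$comp(cases$alt[i]), idxM)
        expect_equal(m$term, p$term, info = paste("pos", cases$pos[i]))
    }
})

test_that("classifier agrees with the full-protein-diff oracle", {
    toy <- toyPlusGene()
    idx <- buildTranscriptIndex(toy$gff, toy$ref)
    chrom <- as.character(toy$ref[[1]])
    # every possible substitution at every position of the toy gene body
    pos <- rep(11:70, each = 3)
    ref <- substring(chrom, pos, pos)
    alt <- unlist(lapply(substring(chrom, 11:70, 11:70),
                         function(r) setdiff(c("A", "C", "G", "T"), r)))
    v <- data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt)
    got <- classifyConsequences(v, idx)$term
    want <- oracleTerms(v, toy$gff, toy$ref)
    expect_equal(got, want)
})

test_that("severity is monotone when transcripts are added", {
    toy <- toyPlusGene()
    # a second transcript covering only the UTR part of exon1
    extra <- toy$gff
    mkf <- function(type, st, en, id, parent) {
        gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(st, en),
                                     strand = "+")
        gr$type <- type; gr$ID <- id
        gr$Parent <- IRanges::CharacterList(list(parent))
        gr
    }
    # transcript whose CDS covers 12..14 (3 bases) inside the other
    # transcript's 5'UTR; adding it can only raise severity there
    extra <- c(extra,
               mkf("mRNA", 11, 23, "T2", "G1"),
               mkf("exon", 11, 23, NA, "T2"),
               mkf("CDS", 12, 14, NA, "T2"))
    idx1 <- buildTranscriptIndex(toy$gff, toy$ref)
    idx2 <- buildTranscriptIndex(extra, toy$ref)
    sev <- c(stop_gained = 4, stop_lost = 4, splice_site = 4,
             missense = 3, synonymous = 2, exonic_unknown = 1)
    chrom <- as.character(toy$ref[[1]])
    pos <- 11:23
    refb <- substring(chrom, pos, pos)
    for (i in seq_along(pos)) {
        for (a in setdiff(c("A", "C", "G", "T"), refb[i])) {
            t1 <- classifyConsequence("chrT", pos[i], refb[i], a, idx1)
            t2 <- classifyConsequence("chrT", pos[i], refb[i], a, idx2)
            expect_gte(sev[t2$term], sev[t1$term])
        }
    }
})

test_that("impact summaries count classes and the splice subcount", {
    expect_equal(summarizeImpacts(data.frame(term = character(0)))$n, 0L)
    calls <- data.frame(term = c("stop_gained", "stop_gained", "missense"))
    s <- summarizeImpacts(calls)
    expect_equal(s$high, 2L); expect_equal(s$moderate, 1L)
    expect_equal(s$low, 0L); expect_equal(s$splice_site, 0L)
    # planted synthetic mix is recovered exactly
    sim <- simulateCohort(smallSimConfig(seed = 5))
    idx <- buildTranscriptIndex(sim$gff, sim$reference)
    calls <- classifyConsequences(sim$truth, idx)
    s <- summarizeImpacts(calls)
    mix <- sim$config$consequenceMix
    expect_equal(s$high,
                 unname(mix["stop_gained"] + mix["stop_lost"] +
                        mix["splice_site"]))
    expect_equal(s$splice_site, unname(mix["splice_site"]))
    expect_equal(s$moderate, unname(mix["missense"]))
    expect_equal(s$low, unname(mix["synonymous"] + mix["exonic_unknown"]))
})
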