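# Fixtures built in code: a hand-laid-out toy gene pair and small
# simulation configurations used across test files.

# Plus-strand toy gene on "chrT" (length 70):
#   1..10   upstream
#   exon1 11..23: 5'UTR 11..15 (GGGCC), CDS 16..23 (ATGTACCT)
#   intron 24..53 (GT..AG, 30 bp)
#   exon2 54..70: CDS 54..57 (GTAA), 3'UTR 58..70
# Spliced CDS = ATG TAC CTG TAA (Met Tyr Leu Stop); the Leu codon CTG
# spans the splice junction (genomic 22, 23, 54).
toyPlusGene <- function() {
    utr5 <- "GGGCC"
    ex1cds <- "ATGTACCT"
    intron <- paste0("GT", strrep("T", 26), "AG")
    ex2cds <- "GTAA"
    utr3 <- "CCTTAGGGCCCTT"
    chrom <- paste0(strrep("A", 10), utr5, ex1cds, intron, ex2cds, utr3)
    stopifnot(nchar(chrom) == 70)
    ref <- Biostrings::DNAStringSet(chrom)
    names(ref) <- "chrT"
    mkf <- function(type, st, en, id = NA, parent = character(0), strand = "+") {
        gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(st, en),
                                     strand = strand)
        gr$type <- type
        gr$ID <- as.character(id)
        gr$Parent <- IRanges::CharacterList(rep(list(parent), length(gr)))
        gr
    }
    gff <- c(mkf("gene", 11, 70, "G1"),
             mkf("mRNA", 11, 70, "T1", "G1"),
             mkf("exon", c(11, 54), c(23, 70), parent = "T1"),
             mkf("CDS", c(16, 54), c(23, 57), parent = "T1"))
    list(gff = gff, ref = ref)
}

# The same gene mirrored onto the minus strand of a reverse-complemented
# chromosome: position p maps to L - p + 1 (L = 70) and alleles are
# complemented.
toyMinusGene <- function() {
    plus <- toyPlusGene()
    L <- 70L
    ref <- Biostrings::DNAStringSet(Biostrings::reverseComplement(
        plus$ref[[1]]))
    names(ref) <- "chrT"
    flipr <- function(gr) {
        st <- L - GenomicRanges::end(gr) + 1L
        en <- L - GenomicRanges::start(gr) + 1L
        out <- GenomicRanges::GRanges("chrT", IRanges::IRanges(st, en),
                                      strand = "-")
        out$type <- gr$type
        out$ID <- gr$ID
        out$Parent <- gr$Parent
        out
    }
    gff <- flipr(plus$gff)
    list(gff = gff, ref = ref, mirror = function(p) L - p + 1L,
         comp = function(b) chartr("ACGT", "TGCA", b))
}

# small, fast simulation used by unit tests; any simulationConfig()
# argument can be overridden through ...
smallSimConfig <- function(seed = 11L, ...) {
    args <- list(
        nVariants = 120L,
        populations = data.frame(
            label = c("FOCAL", "EUR", "AFR"),
            n = c(40L, 40L, 40L),
            fst = c(0.05, 0.01, 0.02), stringsAsFactors = FALSE),
        founder = list(nPlanted = 15L, focalLabel = "FOCAL",
                       focalMafRange = c(0.05, 0.3), refMafMax = 0.002),
        genes = list(nGenes = 6L, exonsPerGene = c(2L, 4L),
                     cdsCodons = c(40L, 60L), minusStrandFraction = 0.5),
        consequenceMix = c(stop_gained = 8L, stop_lost = 4L,
                           splice_site = 8L, missense = 20L,
                           synonymous = 12L, exonic_unknown = 8L),
        cases = list(label = "CASES", n = 20L),
        seed = seed)
    over <- list(...)
    args[names(over)] <- over
    do.call(simulationConfig, args)
}

# memoized default-condition simulation shared by expensive tests
.simCache <- new.env(parent = emptyenv())
defaultSim <- function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateCohort(simulationConfig(seed = seed))
    .simCache[[key]]
}

# write a small VCF text file directly (independent of writeCohortVcf)
writeRawVcf <- function(path, records, samples = c("S1", "S2")) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"),
        records), path)
    path
}
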