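test_that("simulation configs are validated", {
    expect_error(simulationConfig(populations = data.frame(
        label = "A", n = 10L, fst = 0)), "strictly in")
    expect_error(simulationConfig(founder = list(
        nPlanted = 10L, focalLabel = "NOPE",
        focalMafRange = c(0.02, 0.2), refMafMax = 0.002)), "not a population")
    expect_error(smallSimConfig(nVariants = 30L), "exceeds nVariants")
    cfg <- smallSimConfig()
    expect_s3_class(cfg, "SimulationConfig")
})

test_that("frequency simulation is deterministic and plants the founder set", {
    cfg <- smallSimConfig(seed = 21)
    a <- simulateFrequencies(cfg)
    b <- simulateFrequencies(cfg)
    expect_identical(a, b)
    expect_equal(sum(a$founder), cfg$founder$nPlanted)
    maf <- function(f) pmin(f, 1 - f)
    refs <- setdiff(cfg$populations$label, "FOCAL")
    # planted variants satisfy the construction bounds, always
    expect_true(all(maf(a$freq[a$founder, "FOCAL"]) > 0.01))
    expect_true(all(a$freq[a$founder, refs] < 0.01))
    # non-planted variants are never truth-level population specific
    spec <- populationSpecific(maf(a$freq[, "FOCAL"]),
                               maf(a$freq[, refs]))
    expect_identical(spec, a$founder)
})

test_that("tiny divergence keeps population frequencies near ancestral", {
    cfg <- simulationConfig(
        nVariants = 400L,
        populations = data.frame(label = c("P1", "P2"), n = c(10L, 10L),
                                 fst = c(1e-6, 1e-6)),
        founder = list(nPlanted = 1L, focalLabel = "P1",
                       focalMafRange = c(0.02, 0.2), refMafMax = 0.002),
        consequenceMix = c(missense = 1L),
        seed = 31L)
    fr <- simulateFrequencies(cfg)
    dev <- abs(fr$freq[!fr$founder, "P2"] - fr$ancestral[!fr$founder])
    expect_gte(mean(dev < 0.01), 0.99)
})

test_that("genotypes follow the population frequency under HWE", {
    vdf <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G")
    freq <- cbind(P = c(0, 1, 0.5))
    pans <- simulateGenotypes(freq, vdf,
                              data.frame(label = "P", n = 64L), seed = 1)
    d <- dosages(pans$P)
    expect_true(all(d[1, ] == 0L))
    expect_true(all(d[2, ] == 2L))
    # freq 0.5, n = 128: sample AF within 3 binomial standard errors in
    # at least 19 of 20 seeds
    se3 <- 3 * sqrt(0.25 / 256)
    ok <- vapply(1:20, function(s) {
        p <- simulateGenotypes(cbind(P = 0.5),
                               vdf[1, , drop = FALSE],
                               data.frame(label = "P", n = 128L), seed = s)
        abs(alleleCounts(p$P)$AF - 0.5) <= se3
    }, logical(1))
    expect_gte(sum(ok), 19L)
})

test_that("sample MAF estimates true MAF without bias", {
    cfg <- smallSimConfig(seed = 41, nVariants = 1000L,
                          founder = list(nPlanted = 20L,
                                         focalLabel = "FOCAL",
                                         focalMafRange = c(0.05, 0.3),
                                         refMafMax = 0.002))
    fr <- simulateFrequencies(cfg)
    vdf <- data.frame(chrom = "chr1", pos = seq_len(cfg$nVariants),
                      ref = "A", alt = "G")
    pan <- simulateGenotypes(fr$freq, vdf,
                             data.frame(label = "FOCAL", n = 128L),
                             seed = 42)$FOCAL
    af <- alleleCounts(pan)$AF
    truef <- fr$freq[, "FOCAL"]
    bias <- mean(af - truef)
    se <- stats::sd(af - truef) / sqrt(length(af))
    expect_lt(abs(bias), 2 * se + 1e-4)
})

test_that("simulated gene models are valid ORFs on both strands", {
    cfg <- smallSimConfig(seed = 51)
    models <- simulateGeneModels(cfg)
    strands <- vapply(models$genes, `[[`, character(1), "strand")
    expect_true(all(c("+", "-") %in% strands))
    # the consuming index accepts every emitted transcript
    idx <- buildTranscriptIndex(models$gff, models$reference)
    expect_equal(nrow(idx@rejected), 0L)
    expect_equal(nrow(idx@transcripts), cfg$genes$nGenes)
    for (tid in names(idx@cdsSeq)) {
        prot <- as.character(Biostrings::translate(idx@cdsSeq[[tid]]))
        n <- nchar(prot)
        expect_equal(substr(prot, n, n), "*")
        expect_false(grepl("\\*", substr(prot, 1, n - 1)))
        expect_equal(substr(prot, 1, 1), "M")
    }
    # genes do not overlap
    genes <- models$gff[tolower(as.character(models$gff$type)) == "gene"]
    expect_equal(length(GenomicRanges::reduce(genes, ignore.strand = TRUE)),
                 length(genes))
})

test_that("injected variants carry their requested consequence terms", {
    cfg <- smallSimConfig(seed = 61)
    models <- simulateGeneModels(cfg)
    planted <- injectConsequences(models, cfg$consequenceMix, seed = 62)
    expect_equal(unname(table(planted$term)[names(cfg$consequenceMix)]),
                 unname(as.integer(cfg$consequenceMix)),
                 ignore_attr = TRUE)
    expect_false(any(duplicated(planted$pos)))
    # the independent full-protein oracle confirms every label
    want <- oracleTerms(planted, models$gff, models$reference)
    expect_equal(want, planted$term)
    # impossible requests fail with guidance
    expect_error(injectConsequences(models, c(stop_lost = 500L)),
                 "cannot host")
})

test_that("scores separate deleterious truth at the stated accuracy", {
    truth <- data.frame(chrom = "chr1", pos = 1:2000, ref = "A", alt = "G",
                        deleterious = rep(c(TRUE, FALSE), 1000))
    sc <- simulateScores(truth, list(dMean = 0.9, nMean = 0.1, sd = 0.05),
                         seed = 7)
    acc <- mean((sc$label == "D") == truth$deleterious)
    expect_gte(acc, 0.99)
    # zero noise: perfect separation
    sc0 <- simulateScores(truth, list(dMean = 0.9, nMean = 0.1, sd = 0),
                          seed = 7)
    expect_true(all((sc0$label == "D") == truth$deleterious))
    expect_identical(sc, simulateScores(truth,
        list(dMean = 0.9, nMean = 0.1, sd = 0.05), seed = 7))
})

test_that("a full simulation is deterministic and self-consistent", {
    cfg <- smallSimConfig(seed = 71)
    sim <- simulateCohort(cfg)
    sim2 <- simulateCohort(cfg)
    expect_identical(sim$truth, sim2$truth)
    expect_identical(dosages(sim$panels$FOCAL), dosages(sim2$panels$FOCAL))
    expect_equal(nrow(sim$truth), cfg$nVariants)
    expect_equal(sum(sim$truth$founder), cfg$founder$nPlanted)
    # truth table rows and panel variants correspond 1:1
    expect_equal(variantKeys(sim$panels$EUR), sim$truth$key)
    expect_equal(variantKeys(sim$cases), sim$truth$key)
    expect_equal(ncol(sim$cases), cfg$cases$n)
    # deleterious truth implies a coding variant
    expect_true(all(!is.na(sim$truth$term[sim$truth$deleterious])))
})

test_that("emitted files round-trip through their consuming readers", {
    sim <- simulateCohort(smallSimConfig(seed = 81))
    out <- tempfile("emit_")
    paths <- emitCohortData(sim, out)
    # VCF
    p <- readCohortVcf(paths$vcf_FOCAL, label = "FOCAL")
    expect_equal(variantKeys(p), variantKeys(sim$panels$FOCAL))
    expect_equal(dosages(p), dosages(sim$panels$FOCAL))
    # GFF + FASTA feed the index builder
    idx <- buildTranscriptIndex(paths$gff, paths$fasta)
    expect_equal(nrow(idx@rejected), 0L)
    expect_equal(nrow(idx@transcripts), sim$config$genes$nGenes)
    # score and RVIS tables
    sc <- readScoreTable(paths$scores)
    expect_equal(nrow(sc), nrow(sim$truth))
    rv <- readRvisTable(paths$rvis)
    expect_equal(sort(rv$gene_id), sort(sim$rvis$gene_id))
    # frequency tables and gene panel
    fr <- readFrequencyTable(paths$freq_FOCAL)
    expect_equal(fr$MAF, alleleCounts(sim$panels$FOCAL)$MAF)
    gp <- readGenePanel(paths$genePanel)
    expect_equal(sort(gp$gene_ids), sort(sim$genePanel$gene_ids))
})
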