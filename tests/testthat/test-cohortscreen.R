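# a 128-individual cohort carrying two singleton high-impact variants in
# panel genes, in two different individuals
incidentalFixture <- function(sameCarrier = FALSE) {
    n <- 128L
    d <- matrix(0L, 3, n)
    d[1, 1] <- 1L
    d[2, if (sameCarrier) 1L else 2L] <- 1L
    d[3, 5] <- 2L
    panel <- cohortPanel(rep("chr1", 3), c(100L, 200L, 300L),
                         c("A", "C", "G"), c("T", "G", "A"),
                         d, label = "COHORT")
    calls <- data.frame(
        key = variantKeys(panel),
        gene_id = c("BRCA2", "RYR1", "OTHER"),
        term = c("stop_gained", "stop_gained", "missense"),
        impact = c("high", "high", "moderate"),
        stringsAsFactors = FALSE)
    list(panel = panel, calls = calls,
         genePanel = list(name = "acmg", gene_ids = c("BRCA2", "RYR1")))
}

test_that("incidental findings count distinct carriers over the cohort", {
    fx <- incidentalFixture()
    r <- screenIncidental(fx$panel, fx$calls, fx$genePanel)
    expect_equal(nrow(r$findings), 2L)
    expect_equal(r$n_carriers, 2L)
    expect_equal(round(r$rate, 2), 1.56)
    # the same individual carrying both findings is counted once
    fx1 <- incidentalFixture(sameCarrier = TRUE)
    r1 <- screenIncidental(fx1$panel, fx1$calls, fx1$genePanel)
    expect_equal(r1$n_carriers, 1L)
    expect_equal(round(r1$rate, 2), 0.78)
    # no findings when the panel genes are absent from the calls
    r0 <- screenIncidental(fx$panel, fx$calls,
                           list(name = "none", gene_ids = "ZZZ"))
    expect_equal(r0$rate, 0)
    expect_equal(nrow(r0$findings), 0L)
})

# small case cohort with controllable carrier counts / scores / panels
screenFixture <- function() {
    # 6 variants x 10 cases; carrier counts 5, 4, 2, 5, 3, 0
    d <- rbind(c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
               c(2L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
               c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
               c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
               c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
               rep(0L, 10))
    cases <- cohortPanel(rep("chr1", 6), 1:6 * 10L, rep("A", 6),
                         rep("G", 6), d, label = "CASES")
    keys <- variantKeys(cases)
    calls <- data.frame(key = keys, gene_id = paste0("G", c(1, 1, 2, 3, 4, 5)),
                        term = "missense", impact = "moderate",
                        stringsAsFactors = FALSE)
    # v4 not deleterious; others deleterious
    scores <- data.frame(key = keys,
                         score = c(0.9, 0.8, 0.9, 0.2, 0.95, 0.9),
                         label = c("D", "D", "D", "T", "D", "D"))
    # reference panel: v5 common (MAF 0.2), others very rare
    refFreq <- data.frame(key = keys, MAF = c(0.001, 0, 0.002, 0, 0.2, 0),
                          AN = 100L)
    # focal panel: v1 common in the focal population
    focalFreq <- data.frame(key = keys, MAF = c(0.05, 0.001, 0, 0, 0.2, 0),
                            AN = 100L)
    list(cases = cases, keys = keys, calls = calls, scores = scores,
         refFreq = refFreq, focalFreq = focalFreq)
}

test_that("the screen cascade removes variants at the documented stages", {
    fx <- screenFixture()
    rep1 <- screenCases(fx$cases, fx$calls, fx$scores,
                        list(REF = fx$refFreq), screenConfig(minCases = 3))
    # v4 fails deleterious; v3 (2 carriers), v6 (0) fail recurrence;
    # v5 fails rarity (MAF 0.2); survivors v1, v2
    expect_equal(unname(removedByStage(rep1)),  c(1L, 2L, 1L))
    expect_equal(names(removedByStage(rep1)),
                 c("deleterious", "recurrence", "rarity"))
    expect_equal(sort(surviving(rep1)$key), sort(fx$keys[1:2]))
    expect_equal(nSurvivors(rep1), 2L)
    expect_equal(rep1@nGenesOut, 1L)  # both in G1
    # conservation
    expect_equal(rep1@nVariantsIn - rep1@nVariantsOut,
                 sum(removedByStage(rep1)))
    # variant in 2 of 10 cases passes at minCases = 2
    rep2 <- screenCases(fx$cases, fx$calls, fx$scores,
                        list(REF = fx$refFreq), screenConfig(minCases = 2))
    expect_true(fx$keys[3] %in% surviving(rep2)$key)
    # empty frequency source is a config error
    expect_error(screenCases(fx$cases, fx$calls, fx$scores, list(),
                             screenConfig()), "frequency source")
})

test_that("the survivor set is stage-order invariant (predicate intersection)", {
    fx <- screenFixture()
    rep1 <- screenCases(fx$cases, fx$calls, fx$scores,
                        list(REF = fx$refFreq), screenConfig(minCases = 3))
    # independent brute force: intersect the three predicates directly
    d <- dosages(fx$cases)
    del <- fx$scores$label == "D"
    recur <- rowSums(d >= 1L) >= 3L
    rare <- c(fx$refFreq$MAF < 0.01)
    expect_equal(sort(surviving(rep1)$key),
                 sort(fx$keys[del & recur & rare]))
})

test_that("enlarging the MMAF panel set filters more, never fewer", {
    fx <- screenFixture()
    sets <- list(ref_only = list(REF = fx$refFreq),
                 ref_focal = list(REF = fx$refFreq, FOCAL = fx$focalFreq))
    tab <- compareFreqSources(fx$cases, fx$calls, fx$scores, sets,
                              screenConfig(minCases = 3))
    reports <- attr(tab, "reports")
    expect_lte(nSurvivors(reports$ref_focal), nSurvivors(reports$ref_only))
    # v1 (focal MAF 0.05) is the variant the focal panel removes
    expect_equal(setdiff(surviving(reports$ref_only)$key,
                         surviving(reports$ref_focal)$key), fx$keys[1])
    red <- reductionStats(reports$ref_only, reports$ref_focal)
    expect_equal(red$n_removed_extra, 1L)
    expect_equal(red$percent_reduction, 50)
    # a disjoint extra panel changes nothing
    noop <- data.frame(key = "chr9:1:A:G", MAF = 0.4, AN = 100L)
    rep3 <- screenCases(fx$cases, fx$calls, fx$scores,
                        list(REF = fx$refFreq, X = noop),
                        screenConfig(minCases = 3))
    expect_equal(nSurvivors(rep3),
                 nSurvivors(attr(tab, "reports")$ref_only))
    # single source equals screen_cases directly
    one <- compareFreqSources(fx$cases, fx$calls, fx$scores,
                              sets["ref_only"], screenConfig(minCases = 3))
    expect_equal(attr(one, "reports")$ref_only@nVariantsOut,
                 nSurvivors(attr(tab, "reports")$ref_only))
})

test_that("reduction statistics reproduce published-count arithmetic", {
    a <- screenReportFromCounts(450, 157, 126)
    b <- screenReportFromCounts(450, 100, 72)
    r <- reductionStats(a, b)
    expect_equal(r$n_removed_extra, 57L)
    expect_equal(r$percent_reduction_int, 36L)
    expect_equal(r$percent_reduction, 36.3)
    # identical reports: zero reduction
    r0 <- reductionStats(a, a)
    expect_equal(r0$percent_reduction, 0)
    # 189 -> 120 survivors: 69 additionally filtered
    expect_equal(reductionStats(screenReportFromCounts(450, 189),
                                screenReportFromCounts(450, 120))$n_removed_extra,
                 69L)
    expect_error(reductionStats(screenReportFromCounts(10, 0), b),
                 "undefined")
})

test_that("gene panels read from text lists skip comments and blanks", {
    f <- tempfile(fileext = ".txt")
    writeLines(c("# actionable genes", "BRCA2", "", "RYR1", "BRCA2"), f)
    gp <- readGenePanel(f, "acmg")
    expect_equal(gp$gene_ids, c("BRCA2", "RYR1"))
    writeLines("# nothing", f)
    expect_error(readGenePanel(f), "empty")
})
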