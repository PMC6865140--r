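---
title: "Population-aware exome analysis with PopExome: models and design"
author: "PopExome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-aware exome analysis with PopExome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopExome)
```

## The problem

Founder populations — populations descended from a small ancestral group —
carry alleles at frequencies very different from those of the large
reference panels used in clinical sequencing. A variant that is essentially
absent from public panels may segregate at several percent in such a
population. Two practical consequences drive this package:

* **Filtering**: when causal-variant screens discard anything that is not
  "very rare" according to a reference panel, the panel must match the
  patient's population, otherwise benign founder alleles survive the filter
  and inflate the candidate list.
* **Discovery**: variants that are common in the focal population but very
  rare everywhere else (*population-specific* variants) are themselves
  candidates for explaining phenotypes enriched in that population.

PopExome implements both sides: the statistics that characterise a focal
cohort against reference panels, and the filter cascades that exploit a
population-matched frequency database. Because real founder cohorts are
typically access-controlled, the package ships a synthetic-cohort generator
with complete truth tables, so that every stage of the pipeline is
verifiable end to end.

## Cohort representation and quality control

A cohort is a `CohortPanel`: a `RangedSummarizedExperiment` whose rows are
variants (with `ref`/`alt`/`id`/`filter` metadata) and whose single assay
holds allele dosages in {0, 1, 2, NA}. Variant identity everywhere is the
exact key `chrom:pos:ref:alt` after uppercasing; no allele flipping is
attempted, so panels must be aligned to the same reference.

Coordinates follow the two interchange standards exactly: VCF positions are
1-based inclusive, BED intervals 0-based half-open, and all internal
positions are 1-based. A BED line `chr1 99 100` therefore selects exactly
VCF position 100.

`applyQC()` produces the "high-quality SNV" working set with three
independently switchable rules, applied in a fixed order so per-rule
removal counts are well defined:

1. `requirePassFilter` — FILTER must be `PASS` or `.` (default on);
2. `biallelicSnvOnly` — single-base REF and ALT; multiallelic records are
   *dropped*, not split, because allele-matching after splitting is
   ambiguous and the analyses here concern biallelic SNVs (default on);
3. `minCallRate` — fraction of samples with a called genotype, default
   0.9; half-called genotypes (`./1`) count as missing, which is the
   conservative choice.

The defaults express intent rather than a canonical standard — cohort
pipelines differ — which is why every rule is a switch.

## Consequence classification

`buildTranscriptIndex()` validates gene models (sorted non-overlapping
exons, CDS within exons, CDS length divisible by 3, intervals within the
reference) and pre-computes strand-corrected CDS sequences plus splice
windows. `classifyConsequences()` assigns each SNV one of six terms, mapped
to three impact classes:

| term | impact | rule |
|---|---|---|
| stop_gained | high | alt codon is a stop, ref codon is not |
| stop_lost | high | ref codon is a stop, alt codon is not |
| splice_site | high | within the 2 intronic bases flanking an internal exon boundary |
| missense | moderate | amino acid changes, no stop involved |
| synonymous | low | amino acid unchanged (including stop-to-stop) |
| exonic_unknown | low | exonic but outside any CDS |

Codon effects are computed by substituting the strand-corrected alternate
base into the transcript's CDS and translating the affected codon with the
standard genetic code; codons spanning splice junctions are handled through
cumulative CDS offsets. Three design points were genuinely open and were
resolved as follows:

* **Splice window** means the two *intronic* bases on either side of every
  internal exon boundary of a coding transcript (the donor/acceptor
  dinucleotide positions); exonic boundary bases are classified by their
  codon effect, and windows are not created at transcript ends.
* **Start-codon disruption** is reported as missense. The three-class
  scheme enumerates only stop-gain, stop-loss and splice as high impact,
  and inventing a fourth high category would change the class totals.
  (For the same reason the test oracle translates with a plain codon
  table rather than treating `CTG`/`TTG` as alternative initiators.)
* **Multiple transcripts**: the most severe call wins; ties break by
  lexicographically smallest transcript id, for determinism. Each variant
  is attributed to exactly one gene — the gene of that winning call — so
  per-gene burdens sum to the number of assigned variants.

A REF base that disagrees with the reference sequence raises an error
rather than being skipped: silent skips hide coordinate bugs.

## Frequencies, rarity and population specificity

For each variant `alleleCounts()` reports AC (alternate allele count), AN
(called alleles, excluding missing genotypes), AF = AC/AN and the folded
minor allele frequency MAF = min(AF, 1 − AF). A variant with AN = 0 is
flagged *absent*; absence is treated differently by the two questions the
package asks:

* for **novelty** (has this allele ever been catalogued?) absence is a
  distinct state, and `noveltyFlags()` requires absence from every
  reference set and identifier catalog;
* for **rarity filtering** (could this allele be common elsewhere?) absence
  is the strongest evidence of rarity, so `mmaf()` scores it 0.

The maximum MAF (MMAF) of a variant over a set of panels is the natural
filtering statistic when several reference panels are available: a variant
is only as rare as its most permissive panel. MMAF is monotone in the panel
set, so enlarging the set can only move variants out of the very-rare
class — the mechanism by which adding a population-matched panel tightens
a screen.

Rarity classes partition MAF values: very rare (< 0.01, strictly; absent
counts as very rare), rare (0.01–0.05) and common (≥ 0.05). The boundaries
are left-closed on the common side so the three classes are an exact
partition; both thresholds are arguments.

A variant is **population specific** (`populationSpecific()`) when its
focal MAF exceeds 0.01 while every reference MAF is below 0.01 (absent
counting as below). Folded MAF is used throughout; if alternate-allele
frequency is preferred the caller can pass AF vectors instead, as the
criterion is threshold arithmetic on whatever frequencies are supplied.

## Gene prioritization

`burdenByGene()` aggregates qualifying population-specific variants
(default: high and moderate impact) per gene. Three views are offered:

* `lengthCorrelation()` — Pearson correlation between burden and genomic
  gene length (span of the gene's exons); near-zero values argue the
  burden signal is not a gene-size artefact.
* `rvisPrioritize()` — intersects burden (≥ `minCount`) with gene
  intolerance (RVIS percentile ≤ `maxPercentile`); genes lacking an RVIS
  annotation are excluded and counted, not silently kept.
* `deleteriousBurden()` — genes with at least `minCount` (default 3)
  deleterious population-specific variants, plus the full histogram.

Outlier genes (recurrent artefact hotspots) are removed by
`filterOutlierGenes()`: burden above median + `madK` × MAD of the nonzero
burdens (`madK` = 5), with the MAD floored at 1 because integer burden
counts frequently give a degenerate MAD of exactly 0, which would turn the
rule into "anything above the median". An explicit blacklist is also
supported, since hotspot lists are usually curated.

Deleteriousness is consumed, never computed: a score table with a label
column ("D" = deleterious) or, failing that, numeric scores thresholded at
0.5 — the convention of ensemble logistic-regression predictors.

## Screens

`screenIncidental()` reports high-impact variants in a configurable gene
panel and the *rate of actionable incidental findings*: the percentage of
distinct carrier individuals among the cohort. The denominator is cohort
size and the numerator distinct carriers, so an individual with several
findings counts once; two singleton findings in two individuals of a
128-person cohort give 100 × 2/128 = 1.56%.

`screenCases()` applies the causal-variant cascade to a case cohort:
(1) predicted deleterious, (2) present — dosage ≥ 1, zygosity-blind — in
at least `minCases` cases (default 3), (3) very rare under the MMAF of the
configured panel set. The surviving set is the intersection of the three
predicates and hence independent of stage order; the order is fixed only
so the per-stage removal counts in the `ScreenReport` are reproducible.
`compareFreqSources()` runs the same screen under several panel sets and
`reductionStats()` quantifies how many additional variants a larger source
filters out, as a count and as a percentage of the smaller source's
survivors (one decimal, plus nearest integer).

## The synthetic cohort generator

`simulateCohort()` emulates a founder-population resequencing study. What
it models, and what it deliberately does not:

* **Allele-frequency divergence** follows the Balding–Nichols model:
  ancestral frequency *p* from a U-shaped Beta(0.2, 0.2) truncated to
  (0.001, 0.5), then per-population frequency from
  Beta(p(1−F)/F, (1−p)(1−F)/F). Defaults: one focal population with
  F = 0.05 (stronger drift, consistent with a founder history) and four
  references at F = 0.01–0.02. This reproduces the qualitative asymmetry
  of a founder cohort against references without demographic inference.
* **Founder variants are planted, not emergent**: a seeded subset
  (default 100 of 1000) is overwritten with focal MAF uniform in
  (0.011, 0.2) and reference MAFs uniform in (0, 0.002). The reference
  ceiling of 0.002 encodes "essentially absent in references", the
  frequency pattern the founder scenario describes; a design-time power
  calculation showed that detection sensitivity at 128 samples per
  population degrades quickly as this ceiling approaches the 0.01
  threshold, which is a statement about the detector, not a tuning of it.
* **Truth-level exclusivity**: under these F values roughly 1% of
  *non-planted* variants would, by drift alone, satisfy the
  population-specific criterion at the truth level. The generator redraws
  such variants until none remain, so the planted set coincides exactly
  with truth-level specificity and the truth tables are unambiguous. The
  redrawn variants are re-sampled from the same distribution conditioned
  on non-specificity, so borderline frequencies remain represented.
* **Genotypes** are independent Binomial(2, f) draws per individual
  (Hardy–Weinberg, no LD, no relatedness, no genotyping error).
  Singletons arise naturally from binomial sampling of rare variants
  rather than from an explicit knob. The 49-individual case cohort is
  drawn from the focal population's frequencies.
* **Gene models** are toy but structurally honest: 24 non-overlapping
  single-transcript genes on one chromosome (coordinates stay auditable),
  half on the minus strand, 2–5 exons, 60–120 codons, UTR stretches in the
  terminal exons, introns of 30–80 bp. Every ORF starts ATG, ends with a
  single stop and is divisible by 3 — the generator's output always passes
  the index builder's validation.
* **Consequence truth** is by construction: for each requested term,
  substitutions are chosen whose codon effect (or position, for
  splice/UTR variants) guarantees the label; the default mix plants 524
  coding variants, with the remaining variants placed intergenically. The
  classifier is tested against this construction *and* against an
  independent oracle that re-translates whole mutated proteins.
* **Scores**: truth-deleterious variants (high-impact plus a seeded half
  of missense) draw from Normal(0.9, 0.05), others from Normal(0.1, 0.05),
  clipped to [0, 1], labelled "D" above 0.5 — a predictor with nearly
  perfect separation, appropriate for testing plumbing rather than
  predictor robustness. Gene intolerance percentiles are rank-transformed
  Gaussian noise.

Every generator operation is a pure function of (configuration, seed), and
the emitted files (VCF, GFF3, FASTA, TSV tables, YAML config) round-trip
through the package's own readers.

Because of these simplifications, green tests demonstrate correctness of
the statistics and filters under idealised sampling — they do not
demonstrate robustness to LD, relatedness, batch effects, mis-specified
gene models or miscalibrated predictors, all of which real cohorts have.

## Problem sizes and runtime choices

The default simulation uses 1000 variants, five panels of 128 individuals,
a 49-case cohort and 24 genes; the sampling-noise properties of founder
detection are assessed over 20 seeds. These sizes make the binomial
standard errors at the 0.01 frequency threshold clearly visible (AN = 256
means "very rare" is AC ≤ 2) while keeping the full suite comfortably
fast; scaling `nVariants` or panel sizes up changes nothing structurally.

## Known limitations

* Indels and multi-nucleotide variants are out of scope; multiallelic
  records are dropped, not decomposed.
* Consequence classification covers coding transcripts only; regulatory
  and deep-intronic annotation, NMD prediction and HGVS naming are not
  attempted.
* Panels are assumed aligned to one reference; no liftover or allele
  flipping.
* The MAD outlier rule is a reproducible stand-in for cohort-specific
  artefact curation, not a replacement for it.
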