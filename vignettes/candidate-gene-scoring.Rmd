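---
title: "Rare-variant qualification and candidate-gene scoring for cyclic vomiting syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant qualification and candidate-gene scoring for cyclic vomiting syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvscan)
```

## The problem

Cyclic vomiting syndrome (CVS) is a migraine-variant disorder defined by
stereotypical, discrete episodes of nausea and vomiting. Its genetic
architecture appears polygenic, dominated by heterozygous missense variants
of incomplete penetrance in genes for cation transport and energy
metabolism, rather than by classical monogenic pathogenic variants. A
candidate-gene analysis for such a disorder cannot simply count ClinVar
pathogenic calls; it needs a rule set that captures rare, conserved,
protein-altering variation, weighs clinical correlation, and accumulates
evidence per gene across a cohort. `cvscan` implements that rule set as a
reusable pipeline over annotated per-participant variant tables, together
with the mitochondrial-specific rules, the gene-level point scoring and
tier system, composite literature scoring, and the cohort-level statistics
(exact tests, Hardy-Weinberg conversions, panel-vs-panel burden
comparison).

## Variant rules (nuclear)

Working from a laboratory annotation export (one row per participant per
variant; see `variant_table_columns()`), the rules are, in order:

* **Recorded.** Allele frequency in the comparison population (gnomAD
  non-Finnish Europeans by default) strictly below 10%. Under
  Hardy-Weinberg equilibrium that frequency corresponds to 19% of the
  population carrying at least one copy (`carrier_frequency(0.10)`); more
  common variants are not recorded at all. A variant absent from the
  reference is treated as frequency 0: absence from gnomAD is the
  strongest available rarity evidence.
* **Qualifying** = coding, rare and conserved. *Coding* means the
  consequence alters the amino-acid sequence (missense, nonsense,
  frameshift, in-frame indel) or either splice classifier scores strictly
  above 0.6. *Rare* means allele frequency strictly below 2%
  (carrier frequency near 4%). *Conserved* means PhyloP of at least 1.5,
  or a reference-base match in at least 90% of mammalian species when
  PhyloP is in doubt. Comparison operators follow the rule statements
  exactly: frequencies strict, conservation inclusive, splice strict.
* **Key Qualifying** = Qualifying and additionally either **P/LP** (at
  least half of the ClinVar interpretations Pathogenic/Likely Pathogenic,
  or a high prediction of loss of function such as nonsense or frameshift)
  or **Clinical** (the carrier holds a clinical diagnosis of a non-CVS
  paroxysmal disease associated with the gene, e.g. episodic ataxia for
  *CACNA1A*). CVS itself never counts as the matching diagnosis — that
  would be circular. All other Qualifying variants are **Other
  Qualifying**.

Closely spaced variants with identical population prevalence co-segregate
and are collapsed into a single scoring occurrence; the groups are given
in the data (`coseg_group`) and never inferred from coordinates, since no
distance threshold is defined. A homozygous occurrence counts once, and a
hemizygous genotype (X-linked genes such as *OTC*) is handled as the
equivalent of a single copy. Repeat-expansion and structural records have
no allele-frequency rule; they carry an explicit `coding_equivalent` flag
in the data instead of a derived verdict.

`qualify_cohort()` applies all of this and returns one row per occurrence
group; `detect_recessive_candidates()` then reports every participant
carrying two or more qualifying occurrence groups in one gene as a
phase-unknown compound-heterozygous candidate (further judgement — e.g.
whether the gene encodes a metabolic enzyme — is deliberately left
downstream).

## Mitochondrial rules

The mtDNA needs allowances. `classify_mito()` applies them in order:

* heteroplasmy (minor-allele proportion) strictly below 20% excludes the
  record as likely of recent somatic origin; exclusion is absorbing.
* P/LP: heteroplasmy in the inclusive band 40-98%, a ClinVar likely
  pathogenic listing, or a flagged secondary-structure conservation
  exception (tRNA stem Watson-Crick binding conserved across mammals; the
  flag is an input, the structure analysis itself is out of scope). Above
  98% a variant is effectively homoplasmic and the band does not trigger;
  homoplasmic records can still be P/LP via ClinVar or the structure flag.
* Clinical: mitochondrial-related findings in at least four of eight
  domains (neuromuscular, neurodevelopmental, neuropsychiatric,
  functional, endocrine, immunological, metabolic, enzymological);
  `enzymological_domain()` encodes the complex I/IV < 30% activity
  criterion.

Because variants in different mtDNA genes produce heavily overlapping
phenotypes, the whole mitochondrial genome is scored as a single gene
(`mito_as_qualification()` pools everything under the reserved symbol
`mtDNA`).

## Scoring and tiers

Each Key Qualifying occurrence earns its gene 3 points, each Other
Qualifying occurrence 1 point; an occurrence that is both P/LP and
Clinical earns 3 once. Study points map to tiers: at least 12 "highly
likely", 6-11 "likely", 3-5 "possibly", at most 2 "no evidence".
Literature evidence is scored separately — one point per published family
with paroxysmal vomiting, same tier map — and the composite tier is the
higher of the two. `build_candidate_list()` keeps genes at or above
"likely", ordered by study points.

Replaying the packaged transcription of the study's nuclear occurrence
table reproduces the full printed points column for all 35 paroxysmal
genes, the 6 + 6 tier split, and — with the mitochondrial table and the
literature counts — the 22-gene candidate list:

```{r fixture-scan}
scan <- fixture_scan()
scan
head(scan$candidates[, c("gene", "study_points", "study_tier",
                         "literature_points", "composite_tier")], 8)
```

The participant-level counts printed above use the package's own
denominators and differ slightly from the source study's abstract (which
is internally inconsistent about them); the per-gene points and tier
counts are the quantities that reproduce exactly, and they are what the
tests assert.

Tier-promotion decisions that involve clinician judgement (e.g. elevating
individual neuropathy genes found outside the panel) are represented as
data annotations, not computed.

## Statistics

* `fisher_exact()` — two-tailed Fisher exact test by the
  minimum-likelihood convention (sum of point probabilities no larger
  than the observed table's); documented explicitly because the doubling
  convention exists. The odds ratio reported is the sample odds ratio
  `ad/bc`, not the conditional MLE. The test suite checks the p-value
  against exhaustive hypergeometric enumeration on every 2x2 table with
  total at most 40.
* `recurrent_variant_tests()` — every recorded variant seen in at least
  three participants is tested against supplied population allele counts
  (hom = 2 alleles, het/hemi = 1, denominator twice the participants);
  population counts are always inputs, never fetched.
* `carrier_frequency()` — the Hardy-Weinberg allele-to-carrier
  conversion `1 - (1 - q)^2`.
* `mixed_population_frequency()` — weighted-average frequency for a
  synthetic population matching a mixed-ancestry cohort (e.g. 91% NFE +
  9% AA), with a companion allele-count helper.
* `panel_burden_comparison()` — participants with at least one hit in
  panel A versus panel B. Panels of unequal size have no canonical
  correction; the package offers a labeled `gene_count_rescale` choice
  (the larger panel's hit count multiplied by the gene-count ratio,
  rounded half away from zero) and always reports the uncorrected test
  alongside, preferring transparency over guessing intent. Printed
  p-values from the source study whose contingency constructions are not
  stated (the gene-tier p = 0.04, the *OPRM1* odds ratio and the
  mixed-population re-analysis p-values) are deliberately not
  reproduction targets.

## The synthetic cohort generator

The underlying cohort data are not publicly available, so
`generate_cohort()` draws seeded cohorts with the statistical structure
the analysis assumes: per participant and gene a qualifying occurrence at
a configured rate, with annotations drawn so that the qualification
predicates recover exactly those rates (rare truncated-lognormal
frequencies, conserved PhyloP draws, ClinVar multisets of size 1-5
exercising the majority rule at both parities, carrier diagnoses for
Clinical keys, heteroplasmy and domain-count draws for the mtDNA).
Defaults mirror the study's composition: 80 participants, occurrence rate
0.04 (about 119 qualifying occurrences over 35 genes), 26% of occurrences
Key, 32% of Key occurrences P/LP, mitochondrial variant rate 0.19 per
participant. Each gene has its own random stream split off the master
seed by gene symbol, so adding a gene never perturbs another gene's
draws, and a fixed seed yields byte-identical tables.

What the generator does *not* emulate: linkage and co-segregation,
sequencing error, genome coordinates, population stratification, and
gene-length differences (every gene shares one rate unless configured
otherwise). Passing recovery tests therefore demonstrates that the
pipeline measures what the generator encodes — not that real cohorts
satisfy the generator's assumptions.

Problem sizes in the test suite were chosen to give stable statistics at
interactive runtimes: parameter recovery on 500-participant cohorts
(expected per-gene points within four standard deviations), nesting and
monotonicity on 1,000 generated records, and the null two-panel
calibration over 2,000 replicates of 80 participants (type-I error at
nominal 0.05 required to stay at or below 0.06).

## Numerical and design choices

* Absent gnomAD frequency = 0; absent conservation scores leave a variant
  unconserved (no imputation in either direction).
* Threshold boundaries follow the printed operators: allele frequency
  2%/10% strict, PhyloP 1.5 and mammal match 90% inclusive, splice 0.6
  strict, heteroplasmy 20% exclusion strict (20 is kept), the 40-98 band
  inclusive at both ends, complex activity 30% strict.
* Variant identifiers are opaque keys; no positional arithmetic, liftover
  or HGVS normalisation is performed anywhere, which avoids 0/1-based
  ambiguity entirely.
* Reported percentages round half away from zero to the nearest integer.
* The packaged fixtures are transcriptions of printed tables. Domain
  labels in the mitochondrial fixture are deterministic placeholders for
  the printed domain *counts* (the tables print counts, not label sets);
  the unnumbered large-deletion carrier has the reserved participant id
  `"unnumbered"`. Fixture tables are named by content, since the source
  tables' in-text numbering is inconsistent.

## Known limitations

* Variant-level totals that the source study reports but that are not
  derivable from its printed tables (the count of Key Qualifying variants
  across top genes, and the participant-level unions) are not asserted
  anywhere; per-gene points and the mtDNA decomposition are the
  reproducible surface.
* The Clinical rule depends on the completeness of the phenotype table;
  missing diagnoses silently demote Key to Other.
* No ACMG criteria beyond the ClinVar majority rule, and in-silico
  predictors (PolyPhen2/SIFT/MutationTaster) are not part of any decision
  rule.
* VCF ingestion maps flat INFO keys; richly annotated VCFs (VEP CSQ
  blocks) must be flattened upstream, and the TSV dialect remains the
  canonical interchange.
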