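# cvscan

Candidate-gene discovery for cyclic vomiting syndrome (CVS) from annotated
variant tables.

CVS is a migraine-variant disorder of stereotypical, discrete
nausea/vomiting episodes whose genetic component appears polygenic:
predominantly heterozygous, rare, conserved missense variation in genes for
cation transport and energy metabolism, rather than classical monogenic
pathogenic variants. `cvscan` implements the corresponding analysis for
cohorts of sequenced participants: per-variant qualification rules,
mitochondrial-specific classification, gene-level evidence scoring with
tiers, composite literature scoring, and the cohort-level statistics. It is
aimed at clinical-genetics researchers who have laboratory annotation
exports (or VCFs) for a phenotyped cohort and want a reproducible,
rule-based candidate-gene ranking.

## The rules and the score

For a variant with population allele frequency *q* (comparison population
gnomAD NFE; absent ⇒ *q* = 0):

* **recorded**: *q* < 0.10 — under Hardy–Weinberg, carrier frequency
  1 − (1 − q)² < 19%;
* **Qualifying**: coding (missense, nonsense, frameshift, in-frame indel,
  or splice score > 0.6) ∧ *q* < 0.02 ∧ conserved (PhyloP ≥ 1.5 or mammal
  match ≥ 90%);
* **Key Qualifying**: Qualifying ∧ (P/LP ∨ Clinical), where P/LP means at
  least half of ClinVar interpretations are Pathogenic/Likely Pathogenic
  (or predicted loss of function) and Clinical means the carrier has a
  non-CVS paroxysmal diagnosis associated with the gene.

Mitochondrial variants: heteroplasmy < 20% excluded as somatic; P/LP for
heteroplasmy in [40, 98], ClinVar P/LP, or a tRNA structure-conservation
exception; Clinical for ≥ 4 of 8 mitochondrial symptom domains; the whole
mtDNA scores as one gene.

Gene score = 3 × (Key occurrences) + 1 × (Other Qualifying occurrences),
with co-segregating variant clusters collapsed to one occurrence. Tiers:
≥ 12 highly likely, 6–11 likely, 3–5 possibly, ≤ 2 no evidence. The
composite tier is the maximum of the study tier and the literature tier
(one point per published family with paroxysmal vomiting).

## Worked example

The package ships transcriptions of the study's printed tables (the
per-occurrence nuclear variant table, the mtDNA variant table, the 35-gene
paroxysmal and 20-gene neurotransmitter-receptor control panels, and the
literature family counts). Replaying them end to end:

```r
library(cvscan)
scan <- fixture_scan()
scan
#> CVS candidate-gene scan: 35 genes in panel 'paroxysmal_panel', 80 participants
#>   candidate genes (composite tier >= likely): 22
#>   participants with a Key Qualifying variant in a candidate gene: 32/80 (40%)
#>   participants with any Qualifying variant in a candidate gene: 64/80 (80%)

head(scan$candidates[, c("gene", "study_points", "study_tier", "composite_tier")], 7)
#>      gene study_points    study_tier composite_tier
#> 1   mtDNA           35 highly_likely  highly_likely
#> 2   SCN4A           20 highly_likely  highly_likely
#> 3 CACNA1A           19 highly_likely  highly_likely
#> 4 CACNA1S           17 highly_likely  highly_likely
#> 5    RYR2           15 highly_likely  highly_likely
#> 6   TRAP1           14 highly_likely  highly_likely
#> 7    MEFV           12 highly_likely  highly_likely
```

The 22 candidate genes are those whose composite tier reaches at least
"likely": 12 nuclear genes from the study scores, 9 more from the
literature, plus the pooled mtDNA (35 points from 10 Key and 5 Other
Qualifying variants). The participant-level percentages use the package's
own explicit denominators. On your own data the entry point is
`score_candidates(variants, phenotypes, panel, literature)` with tables
from `read_variant_table()` / `read_phenotype_table()`, or `run_pipeline()`
to write the full report bundle; `generate_cohort(cohort_config(seed = 1))`
draws a fully synthetic cohort for pipeline rehearsal.

Statistics helpers: `fisher_exact()` (two-tailed, minimum-likelihood
convention), `carrier_frequency()`, `recurrent_variant_tests()`,
`mixed_population_frequency()`, `panel_burden_comparison()`.

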