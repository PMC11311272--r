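---
title: "Methods behind gmci: marker selection, the cancer index, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gmci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmci)
```

## The scientific problem

Gut dysbiosis — a shift of the intestinal microbial community away from a
healthy configuration — accompanies many malignancies, but single summary
statistics such as Shannon diversity often fail to separate cancer patients
from healthy controls. `gmci` implements a case-control profiling workflow
for species-level shotgun-metagenomic count tables and fecal metabolite
panels, organised around a per-sample **gut microbiome cancer index** that
summarises how much of the control-associated flora a sample retains
relative to how much of the case-associated flora it carries.

The pipeline analyses each malignancy cohort against its sex- and
age-matched healthy controls (HC): alpha diversity, compositional beta
diversity, directed marker-species selection, the index, metabolite
comparisons, and pooled taxa–metabolite correlations.

## Marker-species selection

For one cohort comparison, species first pass two abundance filters:

1. a **universe filter** — the species must carry more than 0.01% of all
   reads pooled over samples (`universe_fraction = 1e-4`), which removes
   taxa whose classification is unreliable at low read counts;
2. a **group filter** — its mean read count must strictly exceed 50 in
   the case group *or* in the matched control group (`min_mean_reads = 50`).
   The OR is deliberate: a species wiped out in cases still qualifies via
   its control abundance.

Each retained species is tested case versus control on **relative
abundances** (counts divided by sample depth — depths differ by orders of
magnitude, so raw counts would confound depth with biology) with a
two-sided Mann–Whitney U test. The test policy is fixed: exact enumeration
when the pooled sample size is at most 12 and there are no ties, otherwise
the normal approximation with tie and continuity correction. P-values are
Benjamini–Hochberg adjusted **within the filtered species of one cohort**
(not pooled across cohorts), matching per-comparison reporting of adjusted
p-values. Species with `q < alpha` (default 0.05) become markers, directed
by the sign of the difference in group mean relative abundance:
control-associated (set *H*, under-represented in cases) or case-associated
(set *C*). A significant species with exactly equal means is directionless
and dropped with a log message — an undirected marker cannot enter either
set.

A linear compositional model would be a reasonable alternative testing
engine for the same tables; the rank test was chosen because it is
assumption-light, exact at small n, and its null behaviour is directly
checkable by simulation (see the error-control tests).

## The gut microbiome cancer index

Given marker sets (*H*, *C*) and a sample's relative abundance vector, let

* `f_H` = fraction of *H* species detected in the sample (0 if *H* is empty),
* `f_C` = fraction of *C* species detected,

with *detection* meaning relative abundance at or above a threshold
`detection_threshold` (θ, default `1e-5`, roughly one read at the default
100,000-read simulated depth). The index is

```
index = log2(f_H + ε) − log2(f_C + ε),      ε = 0.01
```

Higher values indicate a healthier profile. This is a richness-fraction
ratio in the family of published gut health indices (GMHI-like): the core
quantity is the ratio of species over-represented in healthy guts to
species over-represented in neoplastic guts, estimated per sample. The
regularisation ε bounds the index (|index| ≤ log2((1+ε)/ε) ≈ 6.66), makes
0 the balanced point, and keeps it defined when one set is empty.
Implementation detail: the index is computed as a *difference of
logarithms*, not the logarithm of a ratio, so that swapping *H* and *C*
negates it exactly in floating point — a property the test suite asserts
bit-exactly.

Detection uses a relative-abundance threshold rather than `count > 0` so
the index is invariant to sequencing depth when abundances are proportions;
θ, ε and the log base are explicit parameters (`index_params()`) rather
than hidden constants, because the ratio's regularisation is a modelling
choice, not a given.

### Honest evaluation: cross-validation versus in-sample scoring

Deriving markers from the same samples that are then scored is circular:
under a global null it still produces an optimistic AUC, because any
spuriously selected marker was selected *for* separating those samples.
`evaluate_index()` therefore defaults to stratified k-fold cross-validation
(default `k = 5`): markers are derived on training folds only and each
sample is scored exclusively by markers it did not help select. The
in-sample design is retained as an explicitly labelled mode
(`mode = "in_sample"`) for comparability. The test suite demonstrates the
difference by simulation: under the null scenario the cross-validated AUC
is unbiased at 0.5 while the in-sample AUC drifts above it.

Training folds in which no species reaches significance yield a neutral
index of 0 for their held-out samples; under the null this is the common
case and is exactly what keeps the cross-validated AUC honest.

Separation is summarised by a two-sided Mann–Whitney test on held-out
indices and by the rank AUC `P(control index > case index)` (ties count
one half).

## Diversity analyses

* **Alpha**: plain Shannon entropy `H = −Σ p_i ln p_i` (nats) on each
  sample's count proportions, zero-count species excluded; cohorts are
  compared by Mann–Whitney, with BH adjustment across cohorts when all
  seven comparisons are run together. No rarefaction or coverage
  adjustment is applied: the estimator itself, not extrapolation
  machinery, is the implemented content, and at the simulated depths
  (≥ ~100k reads for ~260 species) the undersampling bias is negligible
  relative to group differences.
* **Beta**: the ordination input transform had to be fixed by design;
  we use the centred log-ratio (CLR) transform with a conventional
  half-read pseudocount (0.5), i.e. Aitchison geometry, followed by
  centred PCA. Component signs are fixed by making each component's
  largest-magnitude loading positive, so ordinations are reproducible to
  the bit. Group separation is tested by PERMANOVA (via `vegan::adonis2`)
  on Euclidean distances over CLR coordinates, 999 permutations by
  default, seed recorded; `p = (1 + #{F* ≥ F}) / (1 + n_perm)`. PERMANOVA
  was chosen over ANOSIM as the de-facto standard distance-based group
  test; it is a stand-in for whatever test produced the original
  beta-diversity claims, which is not derivable from the printed record.

## Metabolite comparisons

The 16-metabolite panel (7 SCFAs: acetic, butanoic, formic, hexanoic,
isobutyric, pentanoic, propanoic; 9 amino acids: Ala, Gly, Glu, Ile, Leu,
Met, Phe, Pro, Val; µg per g stool) is compared in two independent modes:

* **concentration** — per-gram values as measured;
* **proportion** — each sample rescaled to percentages of its panel total
  (rows sum to 100 before testing).

The two modes answer different questions (absolute production versus
profile composition) and may disagree in direction; the pipeline never
coerces them to agree. Because metabolomic controls are fewer and cannot
be matched per cohort, the **whole HC pool** is the reference for every
cohort. Per metabolite: two-sided Mann–Whitney, BH across the 16
metabolites within one cohort×mode, direction by median difference, and a
significance code on the adjusted p-value: 1 for q < 0.05, 2 for q < 0.01,
3 for q < 0.001, 4 for q < 0.0001, 0 otherwise. Missing values exclude a
sample from proportion mode only (the denominator is undefined); in
concentration mode the sample still contributes its observed metabolites.

## Taxa–metabolite associations

Taxa with more than 1000 mean assigned reads (strict) and present in at
least 10% of samples are correlated (Spearman, midranks) with each
metabolite over the pooled case and control samples. Taxa are then
clustered on the distance `1 − r` between their correlation *profiles*
(rows of the correlation matrix), metabolites on column profiles, with
Ward linkage (`ward.D2`) cut at a fixed number of clusters — defaults
`k_taxa = 5`, `k_metab = 2`, the module structure typically observed for
such panels. A fixed-k cut replaces dynamic tree cutting deliberately: it
is deterministic and directly testable, and k is exposed in the interface.
Correlating profiles (rather than clustering raw abundances) mirrors the
visual logic of correlation heatmaps, where taxa group by how they relate
to the metabolite panel. Zero-variance vectors have no defined rank
correlation; such cells are flagged `NA` and logged, and rows containing
them are dropped before clustering.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised, with
known ground truth, without any sequence download. It emulates the
*statistical structure* of a seven-malignancy case-control study:

* **Species universe**: 260 detectable species. Baseline proportions are
  drawn once per cohort from a log-normal profile with `baseline_sdlog =
  1.8`, at which the ten most abundant species carry close to half of all
  reads — the mass concentration typical of stool metagenomes.
* **Composition and counts**: per-sample compositions are Dirichlet around
  the group profile with total concentration `base_concentration = 50`,
  within the range of Dirichlet-multinomial overdispersion fits to stool
  data (lower = noisier, more dropouts); counts are multinomial at a
  Poisson depth (`depth_mean = 1e5` reads — a desk-scale stand-in for
  production depths of tens of millions; depth is a config knob). The
  Dirichlet-multinomial was chosen over independent negative binomials
  because it preserves the sum constraint: depleting many species
  implicitly enriches the rest, exactly the compositional regime the
  index exploits.
* **Planted effects**: `n_depleted` species are divided by `effect_fold`
  in cases and `n_enriched` multiplied, then renormalised. Planted species
  are sampled from mid-abundance taxa — outside the dominant top 10, with
  baseline expected reads at least twice the 50-read marker filter — so
  that planted markers are in principle detectable at the configured
  depth; markers in the rare tail would be unidentifiable by construction.
* **Metadata**: sample sizes, sex splits and age ranges follow the
  seven-group study design table (`study_design()`); ages are uniform
  within each group's range and controls mirror the case structure, so
  cases and controls are matched in distribution without modelling
  covariate effects (matching, not adjustment, is the design).
* **Metabolites**: log-normal per metabolite around realistic per-gram
  medians with `metabolite_sdlog = 0.6`; case shifts are multiplicative on
  the log-mean (default: formic acid × `formic_shift`).

Three presets fix the study conditions used throughout the tests:

| preset | n (case/ctrl) | planted (dep/enr) | fold | formic |
|---|---|---|---|---|
| `null` | 20/20 | 0/0 | — | 1 |
| `paper_like` | 40/40 (study sizes in `generate_study`) | 45/6 | 2 | 2 |
| `strong_dysbiosis` | 40/40 | 30/8 | 4 | 2 |

The `paper_like` marker asymmetry scales the 179:24 study-wide
under/over-represented split down to the 260-species universe
(scale = 260/1030, the approximate number of species entering the
per-cohort tests study-wide); the asymmetry, not the absolute count, is
the design signal. The effect-size distribution of real marker species is
unknown; `effect_fold` is a free parameter, not an estimate.

**What the generator does not emulate**: read-level sequencing error,
batch effects, covariate-driven (age/sex) abundance shifts, longitudinal
(post-treatment) structure, or inter-species correlation beyond the
compositional constraint. Passing tests therefore demonstrate the
pipeline's statistical correctness under a clean compositional null and
planted-effect alternatives — not robustness to real-world confounding.

## Numerical and degenerate-input policies

* Read counts must be non-negative integers; all-zero samples are
  rejected at construction.
* CLR pseudocount 0.5 reads (conventional half-count zero replacement),
  exposed as a parameter.
* PCA requires `k ≤ rank`; the rank-1 two-sample case yields
  `variance_explained = 1` exactly.
* Mann–Whitney: ties handled by midranks; `x = y` gives `p = 1`.
* BH: input p outside [0, 1] is an error, q capped at 1.
* The index: both marker sets empty is an error at the single-sample
  level; during cross-validation an empty training selection yields the
  neutral index 0.
* All randomness (generator, fold assignment, permutations) flows through
  explicit integer seeds; identical config + seed is bit-identical
  output, and every written table carries the package version, config
  hash and seed in a header comment.

## Problem sizes used in the shipped tests

The error-control suite runs 200 null cohorts of 20/20 samples × 260
species (marker selection, cross-validated index, PERMANOVA with 199
permutations, metabolite tests); recovery runs 10 seeded
`strong_dysbiosis` cohorts of 40/40; the formic-acid direction check runs
50 seeded cohorts; the full seven-cohort `paper_like` study (680 samples)
runs twice to verify determinism. These sizes give stable Monte-Carlo
estimates (binomial CI half-widths of a few percent) while keeping the
whole suite under a couple of minutes on one CPU.

## Known limitations

* Marker selection and the index assume two-group, matched comparisons;
  no covariate adjustment is available.
* The index's detection threshold interacts with depth for *count*
  inputs; supply proportions (or comparable depths) when mixing
  platforms.
* Ward modules depend on the chosen k; the defaults reflect a typical
  panel structure, not an optimality criterion.
* The Mann–Whitney engine tests each species marginally; strong
  compositional coupling can make marginal directions misleading for
  dominant taxa (the universe filter mitigates, but does not remove,
  this).
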