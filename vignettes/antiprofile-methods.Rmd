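---
title: "Anti-profile methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-profile methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiprofiler)
```

## The model and its assumptions

`antiprofiler` classifies samples by *deviation from normal* rather than
similarity to a cancer profile. The underlying biological premise is that a
defining, stable property of cancer is increased across-sample variability
in the expression of particular genes: in healthy tissue these genes are
tightly regulated, while across tumors their expression scatters widely and
inconsistently. A signature built on this premise does not need tumors to
agree with each other — only to disagree with normal.

The method assumes its input is **already standardized on a single-array
scale** (barcode-style z-scores): each value is comparable across arrays and
studies without cohort-level renormalization. This is what lets a fitted
signature score new samples, including samples from a different study or
tissue (e.g. peripheral blood), with no retraining. The package deliberately
does not implement single-array normalization or quality metrics; it
consumes their outputs (a standardized matrix, optional per-array quality
scores).

Fitting proceeds in three stages, each a function of the supplied data only:

1. **Candidate restriction.** Optionally keep only probes whose
   transcription start site falls in supplied genomic blocks (0-based,
   half-open `[start, end)`; membership is `start <= tss < end`), or only
   tissue-specific probes computed from the normal samples at hand.
2. **Hyper-variability selection.** Two-class: `r = log2(s_cancer /
   s_normal)` per probe, with sample SDs (n − 1 denominator); keep `r >
   threshold` (strict) or the top `n_top`. Multi-tissue: `u = log2(mean_c
   s_gc / mean_t s_gt)` with per-type SDs averaged **unweighted** over
   cancer types and tissues, computed only in types with strictly more than
   `min_tissue_samples` samples.
3. **Normal ranges.** Per selected probe, `median ± k · MAD` over normal
   samples, with the raw MAD (median absolute deviation from the median, no
   1.4826 normality constant — the definition is stated in plain MAD terms,
   and the multiplier `k` absorbs any constant). In the multi-tissue
   setting the universal range is `m_g ± k · mad_g` where `m_g` and `mad_g`
   are medians across qualifying tissues of the per-tissue medians and MADs.

The anti-profile **score** of a sample is the count of signature probes with
expression strictly outside `[lower, upper]`; both tails count, boundary
values count as inside. Scores strictly above a cutoff are called cancer. A
sentence in the source describing the classification rule assigns low scores
to "tumor"; read in context this is an evident slip for "normal", and the
package implements low = normal.

## Parameters that matter

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| `threshold` on `r` or `u` | 1 | log2 SD ratio | SD in cancer at least double that in normal |
| `n_top` | 100 | probes | universal signature size |
| `k` (MAD multiplier) | 5 | MADs | wide enough that normals rarely exit; scores are quite insensitive to `k` (they are monotone non-increasing in it, so it trades sensitivity for specificity smoothly) |
| `expression_threshold` | 2.54 | barcode z | expressed/unexpressed call |
| `specific_frac` | 0.95 | fraction, strict | "expressed in more than 95% of samples" |
| `max_tissues` | 3 | tissues | tissue-specific = expressed in at most 3 tissues |
| `min_tissue_samples` | 10 | samples, strict | per-type SDs/medians only where estimable |
| quality thresholds | 1.2 / 1.25 | GNUSE-style | drop arrays > 1.2; drop whole studies with median > 1.25 (study rule applied first) |
| duplicate distance | 1 | Euclidean | arrays closer than 1 are repository duplicates; the lexicographically first sample id is kept (the choice is arbitrary; determinism is the goal) |
| `B` | 1000 | signatures | random-signature null |
| `n_folds` | 10 | folds | stratified CV |

All defaults are reachable from the command line; every stochastic operation
takes an explicit seed.

## Numerical choices and degenerate inputs

- **Zero normal SD** makes `r` undefined; such probes are flagged degenerate
  and excluded from selection rather than patched with a pseudocount — a
  zero-width denominator would otherwise promote constant probes to the top
  of the list. Zero cancer SD is likewise flagged (the statistic would be
  −∞), which only ever removes probes that could not be selected anyway.
- **Zero MAD on a selected probe** keeps its (collapsed) range but flags it:
  any deviation from the median counts as outside.
- **Ties in selection** break by statistic descending, then probe id
  ascending, so runs are bit-reproducible.
- **Strict vs non-strict inequalities** follow the wording of each rule:
  selection is strictly `> threshold`; the expressed call is strictly
  `z > 2.54`; tissue specificity strictly `> 95%` of samples; *consistent*
  expression is `>= 95%` ("at least"); type eligibility strictly `> 10`
  samples; scoring counts strictly outside the range; classification is
  strictly `score > cutoff`. With continuous data the boundary cases have
  measure zero; fixing them buys determinism.
- **Promoter windows** (1000 bp upstream, 250 bp downstream of the TSS) are
  strand-aware — upstream means the 5′ side, so on the minus strand the
  window extends to higher coordinates. Among in-window CpGs the one nearest
  the TSS wins; ties go to the lower coordinate.
- **Sample SD** uses the conventional n − 1 denominator.
- **Empirical p-values** use the +1 correction,
  `p = (1 + #{null ≥ observed}) / (1 + B)`, so p is never exactly 0 and is
  (slightly) conservative under the null.
- **Candidate pool for the randomization test** is an explicit argument:
  whether random signatures should be drawn from all probes or only from a
  restricted (e.g. block-resident) pool is an analysis decision, not a
  package decision.
- The 2×2 enrichment test reports the **sample (cross-product) odds ratio**
  — the natural descriptive companion to the one-sided hypergeometric
  p-value — rather than the conditional-MLE estimate some implementations
  return.

## Cross-validation without leakage

Both schemes rerun the *entire* build — restriction (including the
recomputation of tissue-specific genes from training normals),
selection and range estimation — inside every training fold. Stratified
k-fold keeps the class proportions per fold, dealing remainders round-robin
within class. Leave-one-tissue-out removes all samples of one tissue (normal
and cancer) from training and scores them with the resulting profile; the
report retains per-fold training sample ids so the exclusion is checkable,
and the test suite checks it.

## What the synthetic data emulate — and what they do not

`simulate_two_class()` draws every probe's normal expression from a tight
baseline Gaussian (mean 0, SD 1 on the z scale) and multiplies the cancer SD
by `sd_inflation` (default 4) at the planted probes, so the expected
statistic there is `log2(sd_inflation)`. Planted probes are placed inside
generated blocks alongside an equal number of non-hyper-variable decoy
probes, making block restriction a real filter. Defaults (10,000 probes,
200 + 200 samples, 200 planted) are the scale at which the recovery
properties are asserted.

`simulate_multitissue()` adds the two-state structure behind universal
anti-profiles: tissue-specific probes are drawn from an *expressed* state in
their 1–3 home tissues and an *unexpressed* state elsewhere; a planted
subset is universally hyper-variable, with cancer samples flipping between
states with probability 0.5 regardless of tissue — so their outside-range
percentages sit away from both 0% and 100%, while normals sit at one of the
extremes. The unexpressed state is N(0, 1); the expressed state is N(6, 1),
chosen so that a robustly expressed probe passes the strict `z > 2.54` call
in essentially every sample — with an expressed mean much lower (e.g. 4),
the per-sample call probability is only ~0.93 and the "more than 95% of
samples" rule would reject genuinely specific genes by construction.
Defaults are 5 tissues × (30 normal + 30 cancer) and 2,000 probes with 300
specific / 100 hyper-variable.

What passing tests on these data do **not** show: robustness to batch
effects, probe-level intensity artifacts, normalization drift between
studies, correlated gene blocks, cellular-composition confounding, or
class-label noise — none of which the generator models. The generators
establish that the estimators recover the structure they target under the
model's own assumptions, with calibrated behavior when no signal is planted;
claims about real arrays rest on the robustness of the medians/MADs and the
single-array standardization, not on these simulations.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run at desk scale: recovery at
10,000 probes × 400 samples; null calibration at the same scale plus a
50-repeat × B = 200 randomization calibration and 10,000 F-test null draws;
cross-validation at 5,000 × 400 (10-fold) and 2,000 × 300 (5-tissue
leave-one-tissue-out). These sizes make every assertion reproducible in a
few seconds to minutes while keeping Monte-Carlo error well inside the
asserted margins.

## Known limitations

- The package does not compute barcode z-scores, GNUSE quality values, or
  fRMA normalization; inputs are assumed standardized, and garbage-in
  applies.
- Probes are treated independently; no gene-level aggregation beyond the
  supplied probe→gene map, and no modeling of inter-gene correlation.
- The enrichment and F-test utilities are generic screens; the package ships
  only BH FDR control, not the q-value method used for ontology screens
  with real annotation catalogs.
- AUC comparison tests between two correlated classifiers (DeLong-style) are
  out of scope; reported AUC differences are descriptive.
- With very few normal samples the MAD is noisy; ranges from fewer than ~10
  normals should be treated as provisional, and the degenerate flags
  inspected.
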