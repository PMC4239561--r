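---
title: "Quantifying fractionation resistance from homology sets, GO annotation and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fractionation resistance from homology sets, GO annotation and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracres)
```

## The problem

After a whole-genome doubling or tripling every gene is duplicated, and
over the following tens of millions of years most duplicates are lost
again, lineage by lineage — *fractionation*. Which duplicates survive is
far from random: gene function and gene expression both bias retention,
and models such as the Gene Balance and Gene Dosage Hypotheses predict
preferential retention of dosage-sensitive genes. `fracres` implements an
analysis that measures the two effects jointly on a panel of species that
share a single ancestral polyploidy event.

The unit of analysis is the **homology set**: the genes, across all
surveyed species, descending from one ancestral gene at the event. Set
construction itself (synteny detection and refinement) is out of scope;
`fracres` consumes a finished set table.

## Fractionation resistance

For a set over `S` species, let `N` be the number of species that still
hold the set *in duplicate* — at least `duplicate_threshold` retained
copies. The fractionation-resistance level is

    F = N + 1,

so `F` ranges from 1 (every species back to a single copy, or none) to
`S + 1`. The threshold defaults to 2: because the ancestral event may be a
tripling, a species can retain three copies, and we deliberately do not
distinguish two from three retained copies; the threshold is exposed for
users who want a stricter notion.

## GO annotation and its propagation

Annotation enters as direct gene-to-term hits. Two propagations follow:

1. **Up the hierarchy** (true-path rule): a hit on a term also hits every
   ancestor along `is_a` and `part_of` edges, the term itself included.
   `regulates`-type relationships are ignored, the standard choice for
   true-path propagation.
2. **Across the set**: a homology set inherits the union of its member
   genes' (closed) annotations, and every member gene inherits the
   set-level union back — so per-gene analyses see set-level function.

Propagation is idempotent, and ancestor chains never cross the three GO
namespaces. Category analyses use the **top-level categories**: the
depth-1 children of each namespace root ("metabolic process", "response
to stimulus", "membrane", "catalytic activity", ...). These are mutually
exclusive as classes, but one set may hit several of them; it then counts
once in each. Sets with no annotation in a namespace are excluded from
that namespace's analyses rather than zero-filled. Whether a real GO
release's depth-1 children coincide exactly with a curated GO slim is a
known wrinkle; we fix depth-1 children as the operational definition.

## Expression handling

Input is a gene × condition RPKM matrix. Three rules, each with a reason:

* **Max over conditions.** Many plant genes are expressed only in
  specific tissues, so a gene's maximum observed expression is a better
  indicator of its importance than the mean or median.
* **Top-1% filter.** A handful of extremely highly expressed genes can
  swamp category averages, especially in small categories; the genes in
  the top `percent` (default 1) of per-gene maxima are removed once,
  globally, before every expression analysis. The threshold is the
  nearest-rank upper percentile with strict-inequality removal:
  deterministic and tie-safe, removing nothing when all values tie, and
  never more than `ceil(percent/100 × n)` genes.
* **`log10(RPKM + 1)` for binning and regression.** The pseudocount keeps
  unexpressed genes finite at 0, so they populate the lowest expression
  block rather than vanishing; base 10 makes bin edges readable in
  decades of RPKM.

Bins default to 8 equal-width intervals over the observed log range
(`[edge_i, edge_{i+1})`, last bin closed). The bin count is a display
resolution, not a model parameter; it is configurable and no statistic in
the package depends on it beyond the bin-proportion tables.

## The three summary statistics

With `Hit(F, C)` the number of sets at level `F` hitting top-level
category `C` (set-level, deduplicated):

* `P(F, C) = Hit(F, C) / Σ_C' Hit(F, C')`, normalized within the
  namespace so that thinly populated high-`F` strata remain comparable;
  a category whose `P(F, C)` rises with `F` is *fractionation
  resistant*, one that falls is *fractionation prone*.
* `P_B(F)`: the fraction of (post-filter) genes of stratum `F` in
  expression bin `B`.
* `E(F, C)`: the arithmetic mean of unlogged post-filter per-gene maximum
  RPKM over the genes of sets in `(F, C)`. Averaging unlogged values
  matches the "simple average expression" definition; the log enters only
  binning and regression. Empty strata are reported missing, never zero,
  and are excluded from regressions.

## Trend tests

The plotted summary curves have only a few points, so significance is
assessed on the underlying observations:

* **Functional trend** (`functional_trend_test`): OLS of the 0/1
  category-membership indicator on `F` over all sets annotated in the
  namespace. One observation per set, independent across sets; classic
  OLS inference applies.
* **Expression trend** (`expression_trend_test`): OLS of `log10(max RPKM
  + 1)` on `F` over all genes in the category. Here observations are
  *clustered*: all genes of a set share one `F` and strongly correlated
  expression. Naive OLS standard errors would be anti-conservative by a
  design effect of roughly `1 + (m̄ − 1)·ICC` (≈ 3 under our simulator),
  so the test uses cluster-robust (CR1) standard errors grouped by
  homology set by default. The slope is the same OLS slope either way;
  `cluster = FALSE` restores naive inference for comparison.

Verdicts use a two-sided slope test at `alpha = 0.05` (the conventional
comparison threshold; per-category p-values are reported raw, and
`stats::p.adjust` can be applied downstream if desired). Degenerate
inputs — constant `F` or constant response — return `p = 1` and
`not_significant`.

## The retention model estimator

The descriptive slope of log-expression on `F` and the *generative*
effect of expression on retention are different parameters. To recover
the latter, `fit_retention_model()` fits a binomial GLM with logit link:
for each set × species trial, success means the species kept the
duplicate, and

    logit p = α0 + Σ_C α_C · I(set hits C) + β · log10(ê + 1),

with category indicators over one namespace's top-level categories. The
expression proxy `ê` is the per-set mean of per-gene *tissue-mean* RPKM:
multiplicative tissue noise averages out almost exactly in the mean, so
the proxy tracks the set's underlying level with negligible bias, whereas
the max-over-tissues summary (kept for all descriptive analyses) carries
an extreme-value inflation that would attenuate `β`. This mirrors the
simulator's generative model, so the estimator is consistent for its
parameters and anchors the package's parameter-recovery checks.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the statistical structure the analysis
assumes, with defaults chosen once as a realistic desk-scale study:

| parameter | default | rationale |
|---|---|---|
| species | 3 | one lineage panel descending from a single doubling |
| `n_sets` | 2000 | thousands of sets, as real panels have |
| pre-event copies | 2 per species | a single doubling round |
| `baseline_retention` (α0) | −2 | most sets return to singleton |
| `category_effects` | +1 ("response-like"), −1 ("metabolic-like") | the qualitative resistant/prone contrast seen in plants |
| `expression_effect` (β) | 0.8 | per unit `log10(RPKM + 1)` |
| latent RPKM | LogNormal(meanlog 2, sdlog 1.5) | median ≈ 7 RPKM, heavy right tail |
| tissues | 6, noise sd 0.3 (ln scale) | tissue-to-tissue spread around one latent level |

Each set draws 1–3 leaf terms in a three-namespace toy ontology (4
top-level categories × 2 leaves per namespace, one leaf per category
attached by `part_of`); their top-level ancestors define its categories.
Retention is per-species independent on the logistic scale — the simplest
mechanism that produces both effects the analysis is built to detect
while staying recoverable by the package's own regressions. Expression is
one latent level per ancestral gene, shared by all its descendants, with
multiplicative log-normal tissue noise. The seed fully determines every
emitted byte.

Deliberately **not** emulated: realistic GO topology and annotation
density, per-copy expression divergence after duplication, multiple
nested WGD rounds (reachable by re-running the simulator on its own
output, but not a default), cross-platform expression scale differences,
and any sequence-level features. Passing the validation suite therefore
shows the machinery is correct and calibrated under this generative
model; it does not certify effect sizes on real panels, where annotation
bias and expression platform effects add variance the simulator lacks.

## Numerical and validation choices

* All randomness flows from a single integer seed; pipeline outputs and
  simulator files are byte-identical across runs of the same seed
  (numeric cells are written at 17 significant digits).
* Proportion invariants (`Σ_C P(F,C) = 1`, `Σ_B P_B(F) = 1`) are asserted
  to 1e-9 on populated strata.
* The validation suite checks every summary formula against independent
  brute-force oracles (≥ 500 random instances each), verifies the trend
  tests' type-I error lies in [0.02, 0.08] at nominal 0.05 over 500
  null cohorts of 2000 sets, and requires the resistant/prone contrast
  and the expression coupling to be recovered in ≥ 95/100 seeded
  replicates (β within 2 SE in ≥ 90/100). These problem sizes give each
  binomial check enough replicates for its tolerance while keeping a
  full run of the suite in the minutes range.

## Limitations

* `F` treats species symmetrically; it ignores phylogenetic structure
  and multiple independent WGDs within a lineage.
* Absolute expression comparisons across datasets produced on different
  platforms are invalid; only within-dataset, normalized comparisons are
  supported.
* Category membership analyses treat top-level categories as independent
  labels; a set hitting several categories contributes to each.
* The regressions are unweighted: each homology set (functional test) or
  gene (expression test) counts once, regardless of set size.
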