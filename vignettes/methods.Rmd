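---
title: "From expression matrix to subtype-regulators: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression matrix to subtype-regulators: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalqpa)
```

`causalqpa` implements a complete inference chain for asking which genes
*drive* the difference between two disease subtypes — developed around the
Crohn's disease (CD) versus ulcerative colitis (UC) contrast in inflammatory
bowel disease — rather than merely which genes differ. The chain is:
housekeeping-gene batch correction, nonparametric differential expression,
quantitative pathway analysis (QPA), prior-network construction from pathway
graphs, and backdoor-adjusted causal screening with permutation calibration.
This vignette records the statistical models, the tunable parameters, and
the design decisions that were genuinely open, so a reader can judge what
the package's passing tests do and do not establish.

## Batch correction by correcting reference genes

Expression values are linear-scale, nonnegative intensities (MAS5-like
summaries). Cross-dataset batch effects are modelled as one positive
multiplicative factor per sample, and removed with a median-ratio scheme:

1. For every candidate housekeeping gene, a one-way ANOVA across
   CD/UC/control on `log2(x + 1)` values measures group stability; after
   Benjamini–Hochberg adjustment across candidates, the `k = 100` genes with
   the *largest* adjusted p (the least group-dependent) become the
   correcting reference genes (CRGs).
2. A reference sample *i* is chosen (a seeded random draw by default; the
   choice is recorded in the fitted model and the run manifest). Every
   sample *j* gets the coefficient
   `coefficient(j) = median(CRG expression in i) / median(CRG expression in j)`,
   and every value of sample *j* is multiplied by it.

After fit + apply, every sample's CRG median equals the reference's; the
correction is idempotent, and changing the reference rescales all corrected
values by a single global constant (the tests assert all three). The ANOVA
runs on the log scale because variance homogeneity across intensity levels
is what the F test assumes; the correction itself stays on linear scale
because the coefficient is a ratio of raw medians.

Two caveats worth stating plainly. First, a median-ratio correction can
only ever equalise CRG medians; if the *uncorrected* data's CRG medians
differ through sampling noise rather than batch distortion, that noise is
absorbed into the correction. Consequently the recoverable object is the
corrected clean matrix (up to one global constant), not the raw clean
matrix, and the error of the per-sample CRG median propagates into every
corrected value as a shared multiplicative factor. This is why reference
genes must be genuinely stable: the synthetic generator gives its
housekeeping genes a coefficient of variation of 0.05 (versus 0.5 for
pathway genes), mirroring the biological stability that justifies their use
as references. With noisy "housekeeping" genes the same machinery would
silently inject per-sample noise correlated across all genes — a real
hazard on real data.

## Differential expression

Per gene, a Kruskal–Wallis omnibus test (midranks, standard tie correction,
chi-square approximation) screens across the three groups; post hoc,
Dunnett-type many-to-one contrasts compare CD and UC against control with a
pooled-variance t statistic on `log2(x + 1)` values. The family-wise
two-sided p uses the single-step max-|t| distribution, evaluated by Monte
Carlo (default 10,000 draws, seeded) with the exceedance convention
`(1 + #exceedances) / (draws + 1)` — so p is never exactly 0, and a
zero-variance contrast with unequal means is flagged degenerate at the
exceedance floor instead of emitting p = 0. A rank-transformed (Steel-type)
variant is available behind `method = "steel"` for heavy-tailed data. The
Monte-Carlo p-values are cross-checked in the tests against
`multcomp::glht`'s single-step Dunnett adjustment.

A gene is a DEG when both gates pass: `|log2FC| > 1`, with fold change
defined as the ratio of group means on corrected linear values with
pseudocount 1 (the fold-change formula itself is a package decision — field
conventions differ), and BH-adjusted post hoc p `< 0.05`. The adjusted
gate is the default because it is the stricter, more reproducible reading;
the raw-p variant is a configuration flag. Post hoc testing is by default
gated on the omnibus test (`gate_on_kw = TRUE`); genes failing the screen
are reported as not tested rather than given a p-value.

## Quantitative pathway analysis

Enrichment of the DEG list in each gene set uses a one-sided upper-tail
hypergeometric test within the measured-gene universe, BH-adjusted, with a
strict default gate (adjusted p < 1e-3). The union of sets enriched in
either subtype-vs-control comparison forms the QPA candidate list.

Each candidate pathway is quantified as a per-sample scalar: the pathway
submatrix is gene-wise standardised (zero-variance genes dropped with a
warning), samples are projected onto its first principal axis, and the sign
is fixed so the score correlates non-negatively with mean pathway
expression ("higher score = higher expression"). The exact one-dimensional
projection is a design choice of this package: the first principal axis is
the simplest projection consistent with comparing pathways on a common
dimension, it is invariant to per-gene affine rescaling, and it ignores
gene order (all tested). Scores have zero mean by construction.

Pathways are compared between CD and UC by the absolute difference of group
mean scores, with significance from `B = 1000` label permutations and the
exceedance convention; the p-value floor `1/(B + 1)` is attained exactly
when the observed difference beats every permutation. Each pathway draws
its permutations from an independent stream derived from
`(seed, pathway_id)`, so adding or removing a candidate never perturbs
another pathway's p-value. Pathways with permutation p below 0.05 are the
differentially expressed pathways (DEPs).

## Prior network and causal screen

The DEPs' directed graphs (SIF-style edge lists, one per pathway) are
merged by node and edge union; duplicate edges keep their first-seen
interaction type and record every contributing pathway in an edge
provenance list. Merged signalling graphs may be cyclic; cyclicity is
reported in the run manifest, never "fixed" by deleting edges.

For each candidate gene (DEGs versus control that are network nodes), the
causal estimate value (CEV) is the coefficient of the treatment gene in a
least-squares fit of the subtype outcome (CD = 1, UC = 0; control samples
excluded) on an intercept, the treatment and its adjustment set, all
expressions `log2(x + 1)`-transformed — a linear-probability estimate of
the change in outcome per unit change of treatment. The adjustment set is
the treatment's measured *parents* in the prior network: parents block
every backdoor path whenever the outcome is not a network ancestor of the
treatment, and they are identifiable from the prior graph alone. A
continuous outcome can be supplied for validation settings where the
estimand is a continuous response.

Significance comes from a placebo-treatment permutation test: the treatment
gene's expression vector is permuted across samples (outcome and
covariates fixed), the regression is refit each draw, and the two-sided
exceedance of the **studentized** coefficient — the CEV divided by its OLS
standard error — gives the p-value. Studentization is essential, not
cosmetic: permuting the treatment destroys its correlation with the
adjustment covariates, so the permuted raw coefficients have systematically
*smaller* sampling variance than the observed one whenever treatment and
covariates correlate (by a factor `1/(1 - R²)` in the residual norm). A
raw-coefficient comparison is therefore anti-conservative — about 12%
type-I error at a nominal 5% in the package's own null experiments with
cor(treatment, covariate) ≈ 0.8 — while the studentized statistic is
pivotal under permutation and restores calibration (measured 4–6%;
asserted in the acceptance tests together with KS-uniformity of the null
p-values). This choice follows the standard permutation-inference
literature on testing partial regression coefficients.

A gene is a subtype-regulator when both its causal permutation p and its
BH-adjusted subtype-differential p (two-sided rank-sum, CD vs UC) fall
below 0.05. The conjunction mirrors the screen's logic: an effect that is
causally plausible but not expressed differently between subtypes, or
vice versa, is not called.

## The synthetic cohort generator

Every stage is verified against cohorts with known ground truth. The
generator is a linear-Gaussian structural model: genes have baseline means
`mu ~ U(20, 40)` and noise SD `sigma = cv * mu` (cv = 0.5 for pathway
genes, 0.05 for housekeeping genes); directed edges within pathways carry
linear weights and are oriented forward in gene order, so the graph is
acyclic by construction; expression is generated in topological order as
`x_g = mu_g + delta_g + sum_u w(u->g) (x_u - mu_u) + noise`, then truncated
at zero (rare at these settings). Disease shifts `delta` (3 noise-SDs by
default) apply equally to CD and UC on the members of the shifted pathways.

The planted cascade `A -> B -> C` (weights 0.8) is the headline motif: the
CD-vs-UC label of a disease sample is *drawn from* a logistic model with
log-odds `1.5 z_A + 1.0 z_B` — coefficients per SD of the model-implied
marginal scale, since per-raw-unit coefficients at intensity scale ~30
would saturate the logistic — and gene C has coefficient exactly 0. Because
the label is sampled downstream of the gene values, "gene causes subtype"
is literally true in simulation, subtype separation of A and B arises
purely through this selection, and C is correlated with the subtype only
through its parent B. A correct screen must therefore call A and B and
refuse C; the package's benchmark asserts exactly that, at n = 200 per
group over 50 seeds (≥ 90% of seeds).

Batch structure is two batches with intensity ratio 1.8 plus per-sample
log-normal jitter (SD 0.1), balanced across groups, applied as per-sample
multiplicative factors — precisely the distortion family the median-ratio
correction removes.

What the generator does *not* emulate: probe-level noise, count data,
dropout, heavy-tailed intensity distributions, nonlinear regulation, cyclic
feedback, or batch effects that are not per-sample multiplicative. Passing
the benchmark shows the chain is correct under its own assumptions; it does
not certify performance on data that violate them (in particular, the
linear backdoor estimator inherits the usual sensitivity of linear
adjustment to strong nonlinearity in the true regulation).

## Problem sizes, numerics, and determinism

Defaults mirror the conventional analysis: CRG panel 100, fold-change gate
1 (log2), significance gates 0.05, enrichment gate adjusted p < 1e-3, and
1000 permutations for both permutation tests. The test-suite calibration
experiments use 500 null replicates with B = 199 permutations each, and
the regulator-recovery benchmark uses 50 cohorts at n = 200 per group with
the full 1000 permutations; these sizes give Monte-Carlo standard errors
comfortably inside the asserted bands (about 1 percentage point on a 5%
rate) while keeping the default run fast.

All randomness flows from one master seed through `derive_seed()`, which
hashes (stage, unit) labels into independent 31-bit child seeds, so every
pathway and every screened gene owns a stable stream. Reruns with the same
inputs and seed are byte-identical, including the written CSV/TSV outputs
(doubles are serialised with 17 significant digits, which round-trips
IEEE-754 exactly). Permutation and Monte-Carlo p-values use the
`(1 + exceedances)/(1 + draws)` convention throughout, so no test ever
reports p = 0; degenerate designs (constant outcome, zero residual
variance, collinear covariates) are either given exact-zero estimates,
flagged, or rejected with the offending genes named, never silently
absorbed.

## Known limitations

* The parents-as-adjustment-set rule is valid when the outcome is not an
  ancestor of the treatment in the true graph; with a wrong or incomplete
  prior network the CEV inherits that bias, and unmeasured parents are
  dropped with a warning rather than imputed.
* The linear-probability estimator targets a well-defined projection even
  though outcome probabilities are not linear in expression; its CEVs are
  comparable across genes but are not odds ratios. A logistic variant was
  considered and left out of scope for the screen because the permutation
  test needs thousands of refits per gene.
* QPA's single principal axis can split a pathway whose genes move in two
  anticorrelated programs; the reported variance-explained fraction is the
  diagnostic to watch.
* The DEG fold-change gate operates on group means of linear intensities;
  with means near zero the pseudocount dominates, which is intentional
  shrinkage but means very low-expressed genes need larger relative shifts
  to pass.
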