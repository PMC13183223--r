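---
title: "Methods: target triage, overlap nulls, and stability at small n"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target triage, overlap nulls, and stability at small n}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nettox)
```

`nettox` turns the common "chemical targets × disease targets × DEGs"
triage into a single seeded pipeline whose every stage can be validated
against planted ground truth. This vignette is the package's account of the
statistics it implements, the defaults it chose where the field's practice
is underspecified, and the limits of what its synthetic validation shows.

## The moderated differential-expression stage

Expression is modelled on the log2 scale as approximately Gaussian — the
regime of two-colour and bead arrays, and a reasonable approximation for
normalised, log-transformed intensities generally. For gene $g$ with
per-group sample sizes $n_1, n_2$, the pooled variance $s_g^2$ has residual
degrees of freedom $d_g = n_1 + n_2 - 2$. Under the hierarchical model
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_{d_g}/d_g$ with a scaled
inverse-chi-square prior $\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, the
posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated statistic $t_g = \widehat{\Delta}_g / (\tilde s_g
\sqrt{1/n_1 + 1/n_2})$ follows a $t$ distribution with $d_0 + d_g$ degrees
of freedom.

The prior is estimated by moment-matching the marginal distribution of
$\log s_g^2$: writing $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the
theory gives $\mathrm{E}[e_g] = \log s_0^2 + \psi(d_0/2) - \log(d_0/2)$ and
$\mathrm{Var}[e_g] = \psi'(d_g/2) + \psi'(d_0/2)$, so $d_0$ comes from one
trigamma inversion (Newton iteration) and $s_0^2$ in closed form. This
deterministic estimator was chosen over profile likelihood because it is
exactly testable: the generator draws per-gene variances from the very same
scaled inverse-chi-square family, making $(d_0, s_0^2)$ a parameter-recovery
target. At 2,000 genes and 9 vs 8 samples the estimates land within ~11 %
($d_0$) and ~6 % ($s_0^2$) of truth across seeds, and the statistics agree
with the established empirical-Bayes implementation to below $10^{-8}$
(both facts asserted in the test suite). If the observed variance of $e_g$
falls below $\psi'(d_g/2)$ the prior df is reported as infinite and all
genes share $s_0^2$; `prior_df = 0` recovers the classical pooled $t$
exactly. Genes flat across *all* samples are reported with $t = 0$, $p = 1$,
flagged, and excluded from prior estimation.

Thresholds are strict (`>` and `<`), so a gene at exactly |log2FC| = 0.5 is
excluded — matching how such cutoffs are conventionally written. Duplicate
probe symbols are collapsed by the mean per symbol before analysis
(`collapse = "mean"`, configurable to `"max"`); the literature rarely states
its collapsing rule, so the package makes its own explicit.

## Target lists and the context filter

Symbols are trimmed, alias-mapped, and upper-cased; duplicates merge keeping
the maximum fit score and the union of interaction-type labels, which makes
standardization idempotent. The context filter applies per-source rules: a
curated interaction database contributes only entries annotated with the
exact label `direct` (the substring test would wrongly accept `indirect`),
and pharmacophore-mapping entries must reach the $1 - 0.2$ quantile of that
source's fit scores, computed with linear interpolation and an inclusive
`>=` so ties at the cutoff are kept — "top 20 %" has no conventional tie
policy, so the package keeps ties rather than dropping data. Detectability
is interpreted as a strictly positive value in at least one sample of at
least one supplied cohort. On log-intensity arrays this is nearly vacuous
(intensities are positive); it exists for count-like inputs, and the
interpretation is deliberately on the provided matrix values since the
package never sees raw platform files.

## Overlap significance

The three-way intersection has no canonical hypergeometric reduction. The
package tests the DEG draw against the joint chemical-and-disease pool:
$K = |A \cap B|$, $n = |C|$, observed $k$ = the three-way count, $N$ = the
background (by default all genes measured on the platform). Other
reductions are one `hypergeomTail()` call away; the choice is exposed
rather than hidden because the reduction changes the answer by orders of
magnitude.

The permutation null redraws all three sets uniformly from the background
at their observed cardinalities (the most conservative reading of "random
expectation"); a `deg_only` mode holds the curated lists fixed. The p-value
uses the +1 pseudo-count on both numerator and denominator so it can never
be zero, and fold enrichment is $k_{obs}$ over the null mean. Calibration
is checked by simulation: with no planted association, the 200-repetition
distribution of $p_{perm}$ passes a Kolmogorov–Smirnov uniformity test at
$\alpha = 0.01$ — but only at realistic set sizes (hundreds of genes from a
background of thousands). With small sets the null overlap concentrates on
a handful of integers, $p_{perm}$ takes ~7 distinct values, and any
continuous-uniformity test rejects; this discreteness is a property of
permutation p-values, not a bug, and the calibration check is therefore run
at the large sizes.

## Centrality ranking

Degree, betweenness and stress are computed from one BFS over each source
node, giving geodesic distances and path counts per component; betweenness
sums $\sigma_{st}(v)/\sigma_{st}$ and stress sums $\sigma_{st}(v)$ over
unordered pairs. Edge confidence scores are used only for thresholding
(strict `> 0.4`), never as weights — mirroring how interaction-score
cutoffs are used in practice. Each metric is min-max normalized (a constant
metric maps to all zeros rather than dividing by zero), the composite is
their mean, and ties break by higher degree then lexicographic symbol so
top-$k$ lists are bit-reproducible. Only the three named metrics enter the
composite; closeness and eigenvector centrality are deliberately out of
scope. The implementation is verified against a Floyd–Warshall brute-force
oracle on random graphs up to 12 nodes and against an independent
betweenness implementation on larger graphs.

## Consensus selection and its small-n behaviour

Three algorithms see the same candidate-gene feature matrix:

* **L1 logistic regression** with internal standardization; $\lambda$
  minimizes mean cross-validated binomial deviance over stratified folds
  (the `lambda.min` convention — deviance, not AUC, because AUC on 3-sample
  folds is mostly noise).
* **Gradient-boosted trees** (depth 3, $\eta = 0.3$, 50 rounds) with
  row subsampling 0.8 and per-tree column subsampling 0.3, selecting
  features with positive total gain. The column subsampling is the one
  genuinely open design choice here: with ~17 samples and many correlated
  informative genes, unsubsampled greedy boosting concentrates all gain on
  one or two features and the consensus intersection degenerates; 0.3 is
  the standard $p \gg n$ remedy and was fixed once, at design time. The
  selection rule (nonzero gain vs a top fraction) is configurable.
* **Shadow-feature selection**, implemented from scratch: each iteration
  appends a freshly permuted shadow copy of every undecided feature, fits a
  random forest (impurity importance), and credits a hit to each undecided
  feature beating the best shadow; two-sided binomial tests against
  Binomial(runs, 1/2) with BH correction at $\alpha = 0.01$ confirm or
  reject. The forest engine differs from the boosted trees on purpose: the
  reference algorithm is forest-based, and this is the one place two
  ensemble types coexist in the package.

A property worth knowing: with a *fixed* small dataset, a noise feature
that happens to correlate with the labels beats its re-permuted shadows
run after run, so the null Confirmed count is not zero — simulation at
$n = 40$, 20 noise features gives a mean of ~1.7 spurious confirmations.
The test suite asserts the simulated value, not the idealised zero; users
should read small-n shadow selections with the same caution.

Nested cross-validation (stratified 5 × 5, 100 repeats) scores the
inner-tuned L1 model on held-out outer folds; an outer test fold containing
a single class has no AUC and is skipped and tallied rather than silently
imputed. Bootstrap stability (1,000 iterations) resamples within class —
at $n = 17$, unstratified resampling frequently yields single-class fits —
fits the tuned L1 model, records the selected set (selection frequency is
therefore LASSO-based, the convention in the workflows this package
emulates), and evaluates on the out-of-bag samples; empty-OOB iterations
are skipped and tallied. Confidence intervals are percentile bootstrap over
the per-evaluation metric values.

## Robustness stages

Two-cohort validation runs a two-sided rank-sum test per gene per cohort
(exact by enumeration when $n_1 + n_2 \le 12$ without ties; normal
approximation with tie and continuity correction otherwise) and calls a
gene core when both p-values pass 0.05 *and* the case-minus-control
direction agrees. Direction uses the median difference — robust, and
consistent with the rank-based test; a mean-difference mode exists because
"consistent trend" is ambiguous in the field's usage. The sensitivity grid
re-runs thresholding and intersection at |log2FC| thresholds 0.25–1.50 with
unadjusted $p < 0.05$ held fixed; strict thresholds make the candidate sets
nested, so a tracked gene lost at one threshold can never reappear — an
invariant the tests assert. Abundance tables (rows on the simplex, e.g. 22
immune cell fractions) get per-component rank-sum tests with BH correction
across the component family; the deconvolution that produces such tables is
out of scope, and its own sample-level QC filter is assumed already applied.

## What the generator emulates — and what it does not

`simCohorts` draws per-gene baselines from
$\mathcal N(\mu_0, \sigma_0^2)$, per-gene variances from the scaled
inverse-chi-square, and adds signed log2 effects to cases; the validation
cohort redraws baselines, variances, and noise but keeps the planted
effects' signs and magnitudes — the structure two-cohort validation relies
on. `simTargetDBs` covers each planted target with probability
`db_coverage` per database and adds decoys, with interaction-type and
fit-score attributes biased toward planted genes. `simNetwork` grows a
preferential-attachment graph and wires planted hubs to at least three
times the median degree. `simAbundance` draws Dirichlet compositions with
one concentration multiplied in cases. Every generator derives its RNG
stream from `(seed, call name)`, so adding a generator never shifts
another's stream and stage-level reruns match pipeline-level runs.

Defaults mimic the small peripheral-blood cohorts typical of this
literature: 9/8 training and 6/6 validation samples. The `paper_mimic`
fixture uses 6,000 genes, 1 % planted effects of 0.6–1.6 log2 units over a
residual SD of ~0.35, database coverage 0.85 and decoy counts sized so the
curated lists land near 1,600 (disease) and 1,000 (chemical union) entries
and the candidate set near 50 — the magnitudes published triages report.
Its interaction network spans the planted targets plus a three-fold decoy
pool, mimicking a candidate-scale PPI retrieval; a genome-wide graph would
dilute hub wiring out of the induced candidate subgraph, which is a real
phenomenon but not the one the hub-ranking stage is meant to demonstrate.

Not emulated: probe-level artifacts, normalization residue, batch effects,
correlated co-expression modules, heavy-tailed intensity noise, or
annotation errors in the curated lists. Passing tests therefore show the
*machinery* is correct and calibrated under its stated model — they do not
certify performance on any real dataset.

## Frozen validation thresholds and problem sizes

All recovery and calibration assertions were frozen from simulations run
before they entered the test suite, then asserted with Monte-Carlo slack:
planted-DEG recovery 0.9998 (asserted ≥ 0.95), variance-prior recovery
within 25 %, hub top-20 recovery 0.98 over 100 graphs of 200 nodes
(asserted ≥ 0.9 over 30 graphs), abundance-shift power 1.0 (asserted
≥ 0.9), abundance type-I error 0.042 at nominal 0.05 — the exact rank-sum
test at 9/8 is slightly conservative by discreteness — (asserted within
0.02), null nested-CV AUC 0.484 ± 0.010 (asserted within 0.05 of 1/2),
all-noise lasso mean selection 1.29 features (asserted ≤ 2.5), and
end-to-end consensus recovery 20/20 seeds non-empty and fully planted
(asserted ≥ 4/5). The routine test suite uses desk-scale problem sizes —
hundreds to a few thousand genes, tens of bootstrap iterations — chosen so
the full suite exercises every stage in a couple of minutes; the acceptance
script runs the pipeline at its full default settings (10,000 permutations,
100 nested-CV repeats, 1,000 bootstrap iterations).

## Known limitations

* The hypergeometric reduction of a three-way overlap is a modelling
  choice; report the permutation p alongside it.
* Shadow-feature and boosted-tree selections are anticonservative at very
  small $n$ (see above); the consensus intersection mitigates but does not
  eliminate this.
* The pipeline assumes pre-normalized expression; no multi-factor designs
  or covariates.
* `supplementMimic()` is a synthetic stand-in for published supplementary
  lists, engineered to the printed cardinalities and a 43-member
  intersection containing MMP9 and HPSE; it validates set arithmetic at
  scale, not the content of any real list.
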