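---
title: "Causal mediation analysis for molecular QTL triplets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal mediation analysis for molecular QTL triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlmed)
```

## The problem

A genetic variant X that is associated with both a chromatin accessibility
peak (M) and the expression of a nearby gene (Y) admits several causal
explanations: the variant may alter accessibility which alters expression
(the *forward* model X→M→Y), it may alter expression of a regulator which
feeds back on accessibility (the *reactive* model X→Y→M), or it may affect
the two phenotypes through independent paths (*independence*/co-local).
Pairwise colocalization cannot distinguish these. When both phenotypes are
measured on the same donors, mediation analysis can: `qtlmed` implements a
Bayesian model selection over all twelve directed-edge configurations of
the X-M-Y triplet, together with the QTL scans that nominate triplets, a
measurement-error filter, a regression-based comparator, and replication
and colocalization summaries. The same machinery applies to trans-acting
triplets in which M is the expression of a *cis*-regulated upstream gene
and Y a distal downstream gene.

## The Bayesian model selection

Each of the twelve configurations (`causal_models()`) specifies the
parents of M and of Y among {X, the other phenotype}. The joint likelihood
factorizes into two linear regressions: for forward-type models
p(m | parents) · p(y | parents), and for reactive-type models
p(y | parents) · p(m | parents, y). Each regression is conjugate Bayesian:

* coefficients β_j ~ N(0, σ² d_j), with d_j = τ₁ for the intercept,
  τ₂ for covariates, and φ²_edge / Var(column) for an effect column;
* σ² ~ scaled-inverse-χ²(κ, λ).

Both β and σ² integrate out analytically
(`marginal_log_likelihood()`), giving a multivariate-t marginal; the
posterior over models is the prior-weighted softmax of the joint log
marginals, computed in log space with a 1e-10 sum-to-one guard.

Dividing φ² by the effect column's variance puts the hyperparameter on the
*odds-of-PVE* scale for a unit-variance response: a prior guess that an
edge explains a fraction p of variance corresponds to φ² = p/(1−p), so the
default φ² = (1, 1, 1) encodes 50% a priori for each edge. M and Y are
centered and variance-standardized before evaluation; X is encoded
−1/0/1 and left unstandardized, which keeps the dosage interpretation of
its effect. Covariates (the caQTL covariates in the M-equation, the eQTL
covariates in the Y-equation) are centered and unit-scaled so that
τ = (1000, 1000) is effectively flat for any reasonable covariate.

Defaults: φ² = (1, 1, 1); (κ, λ) = (0.001, 0.001); τ = (1000, 1000). The
φ² default is supported empirically by `select_phi2()`, which maximizes
the summed model-averaged log evidence over a triplet collection; on
synthetic collections generated with 50%-PVE edges the argmax sits at
odds 1 on the planted edges.

Two model-prior modes exist: `"complete"` zeroes the four reactive
configurations (used when reactive causality is implausible, e.g. the
variant sits inside the peak it would have to react to), `"reactive"`
allows all twelve. The model prior within the allowed set is uniform —
the least-informative choice, made configurable because no stronger
convention exists.

Classification uses strict thresholds: *forward* when
P(complete mediation) + P(partial mediation) > 0.5; *reactive* when
P(complete reactive) + P(partial reactive) > 0.5; otherwise
*independence* when the co-local model is the argmax, else *other*
(reported explicitly, never coerced). The reactive sum has a documented
alternative (`reactive_rule = "literal"`) pairing complete-reactive with
partial-mediation.

## Synthetic data: what it emulates and what it does not

`generate_triplet_data()` builds phenotypes from unit-variance structural
components. Edge coefficients are solved from PVE targets
(β² Var(X) = PVE for a unit-variance response), genotypes are
binomial(2, MAF) under Hardy–Weinberg (MAF 0.5 by default — the balanced,
most informative case; real panels are emulated by passing variant tables
with their own MAFs and optional LD-block correlated copying). Measurement
error is Gaussian with variance Var(true)·(1−ICC)/ICC, so the realized
reliability matches the target analytically; technical replicates redraw
the same error per draw for a uniformly chosen donor subset. Effect signs
are random unless fixed.

The generator captures variance partitioning, LD, replicate structure,
motif planting and GWAS colocalization, and deliberately does not model:
count-level (read-depth) noise, batch structure, relatedness, population
stratification, or non-Gaussian phenotype distributions. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated model, not robustness to those real-data features; the covariate
interfaces are the hook for handling them in practice.

Default simulation sizes track the cohort scales typical of
cell-type-resolved QTL studies: n = 75 donors, MAF 0.5, with n = 150–300
used where a test needs more power. These, with the grid sizes below, keep the full
suite and the acceptance script within a few minutes on one CPU.

## The measurement-error flip filter

Imbalanced measurement error between M and Y can flip the apparent causal
direction. `simulate_flip_threshold()` quantifies this: plant a triplet
with the stated true direction and edge PVEs, inject error on the
chromatin phenotype M across a 20-point ICC grid in (0.05, 1], run the
twelve-model selection (reactive priors) at each point, fit tricube
local-linear regressions (span 0.75, configurable) of the forward-sum and
reactive-sum posteriors against realized ICC, and locate the crossing of
the two fitted curves on a 200-point prediction grid with linear
interpolation. Ten repetitions are averaged.

Design choices that were genuinely open:

* **Where the error goes.** The error is injected on M under both truth
  directions. Under forward truth M is the mediator and noise destroys
  the mediation signal at low ICC, so the reactive model dominates below
  a threshold — the flip the filter targets. Under reactive truth M is
  the chain endpoint and its measurement error is absorbed by the
  reactive model's own residual, so reactive calls are robust; flips to
  forward appear only in the near-degenerate regime where both edge PVEs
  exceed 0.9 and M, Y, X are almost collinear. Injecting the error on Y
  instead (available via `error_on = "y"`) makes reactive truth flip at
  moderate PVEs and is not the default.
* **Crossing acceptance.** A crossing counts only when the two fitted
  curves exchange dominance cleanly — above the candidate one curve
  rises while the other falls (least-squares trend over the region
  above). In addition, when the wrong model's domain is the high-ICC
  side (where posteriors are well resolved) it must dominate by at least
  0.1 posterior mass; on the low-ICC side every mediator-bearing model
  collapses toward zero, so dominance there is assessed relatively.
  This stops noise-level wiggles between two near-zero posteriors from
  being called flips.
* **Sweep summaries.** `flip_boundary_sweep()` declares a PVE grid point
  flipping only when a majority of its repetitions produce an accepted
  crossing — a reproducible phenomenon, not a single-draw accident.

`filter_triplets()` then applies the filter: triplets with non-positive
or missing ICC on either phenotype are excluded, and reactive-classified
triplets whose chromatin ICC falls below their flip threshold are
excluded. Forward calls are not threshold-filtered: the flip that
manufactures false forwards requires both PVEs above 0.9, which observed
triplets do not reach.

## The regression comparator

`permutation_gev_fwer()` implements the classical check: the mediation
statistic is the conditional p-value of X in Y ~ X + Z_Y + M_resid (large
when the mediator absorbs the variant's effect). Its null is built by
conditioning on decoy mediators (10 by default; here, residualized peaks
from another chromosome), sample-index-permuting the decoy set 1000
times, recording each permutation's maximum conditional p, fitting a
generalized extreme value distribution to the maxima by maximum
likelihood (with an empirical-tail fallback), and reporting
1 − GEV-CDF(observed) as the FWER-controlled mediation p-value at the
0.05 threshold.

A limitation worth stating plainly: the permutation destroys every
correlation of the decoys, so the null this test controls is "the
mediator is exchangeable with random off-chromosome peaks". For
independence triplets in which X also drives M strongly — the usual caQTL
condition — conditioning on the correlated M inflates the conditional p
mechanically (Var(X | M) < Var(X)), and the comparator over-calls
mediation. The Bayesian selection, which models the X→M edge explicitly,
does not share this failure mode and is the primary method; the
comparator is a cross-check on forward calls, where the two agree on
strongly mediated triplets.

## QTL scanning and multiple testing

`fit_qtl()` is covariate-adjusted least squares with the t-test of the
dosage term (computed by Frisch–Waugh–Lovell projection; identical to the
full fit and fast enough for permutation loops). Synthetic donors are
unrelated, so no kinship random effect is needed; the fixed-effect model
is the exact limit of the mixed model at zero genetic relatedness.
Rank-deficient or monomorphic designs are flagged degenerate with the
p = 1 convention, never a spurious p-value. Local multiple-testing
adjustment uses an effective-test count — the number of leading
eigenvalues of the cis-window dosage correlation matrix explaining 99% of
variance (level configurable) — followed by the hierarchical procedure in
`hierarchical_egene_fdr()`: per-gene Bonferroni-style local adjustment by
M_eff, then Benjamini–Hochberg across genes at 5%. caQTLs use plain BH at
5%; the trans scan uses BH at 10% after MAF (> 0.025, strict), windowed
LD pruning (50/5/0.5, earlier variant kept on ties), pseudogene exclusion,
a > 1 Mb or cross-chromosome distance rule, and removal of gene pairs
with symmetric log2 cross-mappability above 5 (missing entries retained
as 0, with a message).

## Replication, colocalization, annotation

`storey_pi1()` estimates the non-null fraction among replication
p-values: π₀(λ) on the default grid seq(0.2, 0.8, 0.1), smoothed by a
natural cubic spline (3 df) evaluated at the maximum λ and clamped to
[0, 1] (a grid-mean alternative sits behind `smoother = FALSE`), with a
1000-resample percentile bootstrap CI. `test_coloc()` operationalizes
LD-thresholded colocalization: r² > 0.8 between QTL and GWAS index
variants plus conditional attenuation — the QTL's conditional p must rise
above its discovery threshold, not merely above 0.05, because a
genome-wide signal can attenuate a hundred-thousand-fold and still sit
below nominal significance; both the flag and the log10 fold-attenuation
are reported. Triplet annotation compares forward against independence
calls by r²(Y,M), absolute TSS distance (t-tests) and promoter (±2 kb),
motif-disruption and allele-specific-accessibility flags (chi-square).

## Numerical notes and degenerate inputs

All model evidence is computed in log space with log-sum-exp
normalization. The penalized Gram matrix is Cholesky-factorized; positive
priors guarantee positive definiteness, and the singular branch is a
guarded hard error. Zero-variance effect columns receive an
epsilon-variance guard so a monomorphic X degrades gracefully to the
no-effect models. ICC may legitimately be negative (within-donor
variability exceeding between-donor) and such features are excluded by
the filter rather than clamped. GEV fits that fail fall back to the
empirical tail with a message. Half-open interval membership
(start ≤ pos < end) follows the BED convention everywhere; ±1 Mb windows
are inclusive.

## Known limitations

Single-variant, single-mediator models only; no haplotype or
multi-mediator extensions. The effective-test count is an eigenvalue
surrogate, not a permutation-calibrated local correction. The comparator's
null is exchangeability, as discussed. The synthetic generator's Gaussian
phenotypes understate the heavy tails of count-derived molecular
phenotypes; variance-stabilized inputs are assumed.
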