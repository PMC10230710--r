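# qtlmed

Causal mediation analysis for molecular QTL triplets.

A genetic variant (X) associated with both a chromatin accessibility peak
(M) and the expression of a gene (Y) may act through the peak (the
**forward** model X→M→Y), through the gene onto the peak (the **reactive**
model X→Y→M), or through two independent paths (**independence**).
Colocalization alone cannot separate these; when both phenotypes are
measured on the same donors, mediation analysis can. `qtlmed` is aimed at
regulatory-genomics analysts working with matched caQTL/eQTL (or
cis/trans-eQTL) data who want to classify X-M-Y triplets by causal
structure and guard the calls against measurement-error artifacts.

## What it implements

* **Bayesian model selection** over the twelve directed-edge
  configurations of an X-M-Y triplet. Each configuration factorizes into
  two conjugate Bayesian regressions with closed-form marginal
  likelihoods: coefficients β_j ~ N(0, σ²d_j) with d_j = φ²_edge/Var(col)
  on the odds-of-PVE scale (φ² = p/(1−p)), σ² ~ scaled-inv-χ²(κ, λ);
  defaults φ² = (1,1,1), (κ, λ) = (0.001, 0.001), τ = (1000, 1000). A
  triplet is called forward when P(complete) + P(partial mediation) > 0.5,
  reactive when the reactive pair's sum exceeds 0.5.
* **QTL scanning**: covariate-adjusted least-squares cis/trans scans,
  eigenvalue-based effective-test counts, hierarchical eGene FDR, BH at
  5% (caQTL) / 10% (trans), windowed LD pruning (50/5/0.5), MAF,
  pseudogene, distance and cross-mappability filters.
* **Triplet construction** under the forward (variant inside peak, ±1 Mb
  of the TSS), reactive (TF eGene + 80%-match motif-bearing peak +
  trans-caQTL, variant outside the peak) and trans eligibility rules,
  with a validator and Fig-style feature comparisons.
* **Measurement-error filtering**: one-way ICC(1) from technical
  replicates, and a simulation that finds the ICC below which a true
  causal call flips direction; reactive calls below their flip threshold
  and triplets with non-positive ICC are excluded.
* **Regression comparator**: conditional association with a permutation
  null of decoy mediators summarized by a maximum-likelihood GEV fit,
  giving FWER-controlled mediation p-values.
* **Replication and colocalization**: Storey's π1 with bootstrap CI, sign
  concordance, donor down-sampling, and LD-threshold (r² > 0.8)
  conditional colocalization with GWAS index variants.
* **Synthetic data with planted truth** for every stage, and
  `run_pipeline()` to drive the whole chain from one seeded config.

## Worked example

Simulate one forward triplet (X explains 40% of M, M explains 40% of Y,
150 donors, mild measurement error, 60 replicate donors) and run the three
main analyses:

```r
library(qtlmed)
set.seed(7)
arch <- synthetic_architecture("complete mediation", pve_a = 0.4, pve_b = 0.4,
                               n_samples = 150, icc_m = 0.9, icc_y = 0.95,
                               n_replicate_donors = 60, fix_sign = TRUE)
d <- generate_triplet_data(arch, seed = 7)

posterior_over_models(d$x, d$m_obs, d$y_obs,
                      priors = mediation_priors(model_prior_mode = "reactive"))
#> Bayesian mediation model posterior (n = 150 )
#>         no-effects          x->m only          x->y only           co-local
#>             0.0000             0.0000             0.0000             0.0000
#>          m->y only complete mediation        x->y + m->y  partial mediation
#>             0.0000             0.5964             0.0000             0.2086
#>          y->m only        x->m + y->m  complete reactive   partial reactive
#>             0.0000             0.0000             0.0000             0.1950
#> classification: forward (forward sum 0.805, reactive sum 0.195)

estimate_icc(d$replicates_m, feature_id = "peak_1")
#>   feature_id       icc n_donors_with_replicates mean_replicates
#> 1     peak_1 0.9044036                       60               3

permutation_gev_fwer(d$y_obs, d$x, residualize(d$m_obs),
                     decoys = matrix(rnorm(150 * 10), 150),
                     n_perm = 500, seed = 1, triplet_id = "var_1 peak_1 gene_1")
#>            triplet_id p_conditional_observed       fwer_p significant
#> 1 var_1 peak_1 gene_1              0.1197727 3.422818e-13        TRUE
```

The posterior concentrates on complete mediation (forward sum 0.805 >
0.5, so the triplet is classified forward); the replicate table recovers
the planted reliability (ICC 0.90 vs target 0.9); and the comparator
agrees — conditioning on the mediator leaves the variant with no residual
association (conditional p = 0.12, far in the upper tail of the decoy
null, FWER p ≈ 3e-13).

The end-to-end pipeline on a planted architecture:

```r
out <- run_pipeline(default_config(seed = 1), "demo_run")
out$manifest          # every stage table with md5 checksums
table(out$tables$triplets$classification)
```

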