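# integraPC

Integrative copy-number + expression subtyping of primary prostate cancer,
with survival-based validation.

Prostate cancer treatment decisions still lean on Gleason grade, PSA and
stage, yet tumours with similar histology behave very differently.
Molecular subtypes defined jointly by somatic copy-number alterations
(CNA) and transcript expression separate patients by risk of biochemical
relapse (BCR) better than either data type alone. integraPC implements
that analysis end to end for researchers working with matched CN segment
calls and expression arrays: feature selection by *cis* copy-number dosage
effects, penalised joint latent-variable clustering, classifier-based
transfer of subtypes to a validation cohort, prognostic evaluation, and a
resampling null for benchmarking gene signatures. A synthetic-cohort
generator with recoverable ground truth supports testing and calibration
throughout.

## The model

Each data block (expression and per-gene CN state over the same tumours)
is a linear image of shared latent positions:

```
X_d = W_d Z + E_d,   Z ~ N(0, I_{K-1}),   E_d ~ N(0, diag(psi_d))
```

fitted by EM with an element-wise lasso on the loadings
(objective = log-likelihood − λ·n·Σ|W|), and subtypes called by seeded
k-means on the posterior-mean latent positions. Model selection scans
K = 2–11 and feature counts 100–1000, scoring each cell by
subsample-stability-weighted variance explained and choosing the smallest
K within 5% of the best (an elbow rule). Upstream: quantile
normalization, max-IQR probe collapse restricted to perfect probes,
parametric empirical-Bayes batch adjustment, rank-filtered segment-to-gene
CN states, percent genome altered (altered bases / 3×10⁹), and Pearson
correlation of each gene's CN state with its own expression (the cis
dosage effect) to rank features. Downstream: moderated-t differential
expression per subtype vs pooled benign, Kaplan–Meier / K-group logrank /
Cox PH with an events-per-variable guard, ~50-gene per-subtype signature
refinement, and the percentile of a signature's logrank statistic against
R random same-size gene sets.

## Worked example

```r
library(integraPC)

coh <- generate_cohort(sim_config(n_tumour = 150L, n_benign = 30L,
                                  n_genes = 1200L, seed = 42L))
run <- run_discovery(coh$segments, coh$expression, coh$clinical,
                     coh$annotation, run_config(seed = 42L))
run$model
#> Integrative latent-variable model: K = 5 (latent dim 4), lambda = 0.03
#>   150 samples, blocks: expr (100 features), cn (100 features)
#>   variance explained = 0.673, converged in 323 iterations
#>   cluster sizes: 32, 30, 30, 30, 28

run$survival$logrank
#> # A tibble: 1 × 5
#>   chi_square    df  p_value     n n_event
#>        <dbl> <int>    <dbl> <int>   <int>
#> 1       48.8     4 6.31e-10   150      93

truth <- setNames(coh$truth$subtype_of_sample$subtype,
                  coh$truth$subtype_of_sample$sample)
compare_partitions(run$model$assignments,
                   truth[names(run$model$assignments)])
#> # A tibble: 1 × 3
#>     ari   vii vii_unit
#>   <dbl> <dbl> <chr>
#> 1 0.967 0.143 bits
```

The five recovered subtypes explain 67% of the joint variance, agree with
the planted subtypes at ARI 0.97, and separate relapse-free survival
sharply (logrank p ≈ 6×10⁻¹⁰ — the generator plants a ~3-fold hazard range
across subtypes). `autoplot(run$model)` shows samples in latent space;
`autoplot(run$survival$km)` draws the per-subtype Kaplan–Meier curves;
`tidy()`/`glance()` expose loadings and fit summaries. A validation cohort
is classified with `run_validation()` (or `classify_new_samples()` on a
`write_model()`/`read_model()` archive), and signatures are benchmarked
with `score_signature()` / `random_signature_null()`.

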