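---
title: "Integrative subtyping of prostate cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative subtyping of prostate cancer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

integraPC discovers molecular subtypes of primary prostate cancer by
modelling somatic copy number (CN) and transcript expression jointly, and
then asks whether the subtypes carry prognostic information for biochemical
relapse (BCR) after prostatectomy. This vignette is the package's account of
the statistical machinery: the models, their assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

## The joint latent-variable model

The core of the package is a Gaussian latent-variable model shared across
data blocks. For blocks $d = 1, \dots, D$ (here $D = 2$: expression and
per-gene CN state, both over the same tumours and the same genes), each
feature-by-sample matrix is modelled as

$$X_d = W_d Z + E_d, \qquad Z_i \sim N(0, I_{K-1}), \qquad
  E_{d} \sim N(0, \mathrm{diag}(\psi_d)),$$

where $Z$ holds the shared latent positions of the samples, $W_d$ the
block-specific loadings, and $\psi_d$ per-feature noise variances
("uniquenesses"). The latent dimension is $K - 1$ for a target of $K$
clusters, the convention under which a four-dimensional latent space yields
five subtypes. Features are standardized to mean 0, variance 1 before
fitting; CN states enter as standardized numeric values (0–4, diploid 2),
a deliberate simplification — the Gaussian treatment matches the
correlation-based feature selection upstream, and the multinomial variants
of this model family are out of scope.

Sparsity in the loadings comes from an $\ell_1$ penalty: the fitted
objective is the log-likelihood minus $\lambda\, n \sum_{d}\|W_d\|_1$, with
$\lambda$ on a per-sample scale so its meaning does not drift with cohort
size.

**Fitting.** `fit_integrative_model()` runs EM:

* *E-step.* With $\Psi = \mathrm{diag}(\psi)$ over the stacked blocks,
  $\Sigma_Z = (I + W^\top \Psi^{-1} W)^{-1}$ and
  $\mathbb{E}[Z \mid X] = \Sigma_Z W^\top \Psi^{-1} X$.
* *M-step, loadings.* Each feature's row of $W$ minimizes a quadratic form
  plus the $\ell_1$ term; we take three sweeps of coordinate descent with an
  element-wise soft threshold (threshold $\lambda n \psi_j$, because
  feature $j$'s quadratic loss is weighted by $1/\psi_j$). Coordinate
  descent from the previous $W$ never decreases the penalized Q-function,
  so the generalized EM argument applies.
* *M-step, variances.* $\psi_j$ is the expected residual variance, floored
  (below).

The penalized observed-data log-likelihood is computed each iteration via
the Woodbury identity and asserted non-decreasing; the fit stops when its
relative change falls below `tol` (default `1e-6`) or at `max_iter`
(default 500). In practice fits at the default cohort sizes converge in
tens of iterations.

**Subtype calls.** Samples are clustered by k-means on the posterior-mean
latent positions ($K$ centers, 50 restarts, seeded). If fewer than $K$
distinct latent positions exist (e.g. full shrinkage), all samples are
placed in one cluster with a warning rather than failing.

**Variance explained** is $1 - \sum_j \psi_j / \sum_j \mathrm{var}_j$,
summed over both blocks — 0 under full shrinkage, at most 1, and
non-increasing in $\lambda$.

### The noise-variance floor

Maximum-likelihood factor models degenerate when a residual variance
collapses to zero (a Heywood case): that feature acquires unbounded
likelihood weight $1/\psi_j$ and dominates the posterior geometry. Integer
CN states are especially prone to this — within a cluster a CN feature can
be explained essentially exactly. We therefore bound every uniqueness below
at `psi_floor` (default 0.2 of the unit feature variance). During
development we observed that with an effectively unbounded floor the CN
block monopolized the latent space and samples carrying only part of their
subtype's alteration profile were systematically misassigned; with the
bound in place both blocks contribute and recovery is insensitive to the
exact value over roughly 0.1–0.3. This is the same remedy `factanal` and
other factor-analysis implementations apply, here with a larger bound
because discrete blocks collapse harder.

### Choosing K, the feature count and the penalty

`select_model()` fits a grid over $K$ (2–11 by default) and feature-set
sizes (100–1000), with the penalty chosen per cell. Each cell is fitted
`n_restarts` times (default 5), and each restart refits the model on a
random subsample of the samples (default 70%) from a random initialisation
— consensus-clustering-style perturbation. The **stability score** is the
mean pairwise Adjusted Rand Index between restarts' cluster assignments on
their shared samples. Restarting from random initialisations alone is not
enough: deterministic substructure (e.g. partial carriers of an alteration
profile) makes over-specified $K$ look perfectly reproducible, whereas
subsampling exposes that those finer splits are not stable features of the
cohort. Per cell, $\lambda$ is the grid value (default 0.03/0.1/0.2)
maximizing stability. The chosen cell is the smallest $K$ (then the
smallest feature count) whose stability-weighted variance explained is
within 5% of the grid maximum — an elbow rule that prefers the most
parsimonious model statistically indistinguishable from the best.

### Transfer to a validation cohort

`train_centroids()` stores, per subtype, the mean standardized concatenated
CN + expression vector together with the training scaling parameters.
`classify_new_samples()` standardizes a new cohort with the *training*
center/scale and assigns each sample to the Euclidean-nearest centroid;
features missing in the new cohort are imputed at the training mean (0
after standardization) and counted, with an error above 20% missing.
Nearest-centroid was chosen for determinism and auditability; distance
ties resolve to the lowest-indexed cluster and are logged.

## Upstream of the model

**Expression preprocessing.** Probe-level log2 matrices are quantile
normalized (every sample mapped onto the mean sorted profile; ties get the
mean of the reference values at their rank range, via limma). Only probes
flagged `perfect` are eligible downstream; each gene is represented by its
highest-IQR perfect probe, with IQR computed by linear interpolation
between order statistics (so IQR of {1,2,3,4} is 1.5) and ties broken to
the lexicographically smallest probe id. Batch effects are removed with the
parametric empirical-Bayes location/scale adjustment (ComBat, via sva),
with the feature grand means restored exactly afterwards; a single batch
requires an explicit override and passes through unchanged. Spatial
artefact correction of bead-level data is upstream of this package's
inputs. Where a variability ranking is needed (`top_variable_features()`),
it is computed on whatever matrix is supplied; the pipeline supplies the
batch-adjusted matrix, and callers wanting the pre-adjustment ranking can
simply pass that matrix instead.

**Sample filters.** Tumour samples below a cellularity threshold are
excluded (inclusive boundary; 20% for a discovery-style cohort, 70% for a
strict validation cohort); benign samples are retained regardless.

**CN gene states.** Segments with confidence rank ≤ 2 (1 = highest of five)
are collapsed onto genes: a gene takes the state of the segment covering
the majority of its length; an exact 50/50 tie resolves to the state closer
to diploid (conservative), and genes with no retained covering segment
default to diploid and are flagged. Recurrence keeps genes altered
(CN ≠ 2, gains and losses combined; a flag separates directions) in at
least 10% of the cohort, boundary inclusive. Percent genome altered sums
the bases of non-diploid rank-1 segments and divides by exactly
3×10⁹ — the printed convention, kept rather than an assembly length, and
configurable.

**cis-eQTL feature selection.** For each gene with CN variation, the
Pearson correlation between its own CN state and its own expression across
tumours (the self-locus is within any cis window < 1 Mb). Pearson rather
than rank correlation because the coupling of interest is the linear dosage
effect; CN is numeric. Features are ranked by |r| (ties by p, then id) and
a fixed count is taken — no multiple-testing cut, since a fixed feature
count, not a significance set, feeds the model. Genes without CN variance
are excluded and reported.

## Downstream evaluation

**Differential expression.** Per-gene one-way OLS across the subtypes and
the pooled benign reference (the matched-pair alternative is a flag;
pooling is the default reading of a common benign reference group), with
empirical-Bayes variance moderation: a scaled inverse-chi-square prior
fitted by moment-matching the distribution of $\log s_g^2$ (closed-form
log-F moments, Newton inversion of the trigamma), giving
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and moderated t with
$d_0 + d_g$ degrees of freedom. Forcing $d_0 = 0$ recovers the ordinary t
and $d_0 = \infty$ the fully pooled t — both asserted numerically in the
tests, alongside a cross-check of the hyperparameters against an
independent implementation. Equal observed variances drive the estimate to
the $d_0 = \infty$ branch, handled explicitly. BH adjustment is applied
within each contrast. Fold-change thresholds support both inclusive
(default) and strict boundaries, since both conventions appear in common
use at cuts of 1, 1.5 and 2.

**Survival.** Kaplan–Meier, K-group logrank and Cox proportional hazards
are delegated to the survival package (Efron tie correction by default,
Breslow behind a flag; Wald intervals at 0.90/0.95/0.99). Conventions fixed
here: PSA is dichotomized at > 10 ng/ml (exactly 10 is "low"); Gleason
≥ 4+3 is high (3+4 is low); a "two highest vs two lowest risk groups"
contrast ranks groups by observed event fraction, pools the extremes and
drops the middle. `epv_check()` enforces at least 10 events per parameter
before a multivariable Cox fit, the standard safeguard that motivates
combining cohorts when events are scarce.

**Signature scoring and the resampling null.** A gene signature is scored
by standardizing its rows, splitting samples into two groups by seeded
k-means (50 restarts) in signature space, and testing the split with a
logrank test. The percentile of a signature against `R` random same-size
gene sets (drawn from all assayed genes, including the target's own genes;
a flag excludes them) is `100 × #(null ≤ target)/R`. The scoring rule and
the one-vs-rest ranking used by `refine_cluster_signature()` (absolute
standardized mean difference, gene = max over its CN and expression
components) are this package's explicit, documented choices; fuller
descriptions of the original procedures were not available, so comparisons
against published cohort numbers are conditional on these stand-ins.
Partition agreement uses the Adjusted Rand Index and the Variation of
Information, the latter reported in bits.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts with the structure the analysis assumes,
with recoverable ground truth: K latent subtypes (default 5), each defined
by a 30 Mb deletion and a 30 Mb gain on its own pair of chromosomes,
carried by each subtype member independently with penetrance 0.9; linear
cis dosage effects (1.5 log2 units per CN unit, the default) for genes
inside event regions; per-gene baselines N(8, 1); Gaussian noise (SD 0.5);
two batches shifted by 0.5 log2 units; matched diploid benign samples; and
exponential relapse times with subtype-specific hazards (defaults spanning
roughly 0.003–0.025 events/month, a ~3-fold good-to-poor range consistent
with ~50% relapse over a 100-month follow-up) under administrative
censoring at 100 months. Defaults for penetrance, dosage effect and noise
match the conditions used throughout the tests; cohort sizes default to
125 tumours with matched benign. A fraction of genes carries a second,
attenuated probe and a small fraction only a non-perfect probe, so probe
collapse has real work to do. `generate_null_cohort()` strips all CN
events, sets one subtype and a common hazard — the negative control for
calibration tests.

What the generator does **not** emulate: multifocal tumours and subclonal
CN fractions (states are clonal integers), CN measurement noise (segment
calls are exact, which is why near-zero residual variances arise in the CN
block), probe-level bead data, LOH without CN change, and
non-administrative censoring. Consequently, passing tests demonstrate the
machinery's correctness and calibration under the stated generative model
— not performance on real arrays, where noisier CN calls and weaker,
correlated dosage effects will reduce recovery. One observed artefact of
strong planted structure: the signature score distribution develops atoms
(k-means snaps most random signatures onto the dominant split), so the
uniformity of null percentiles — exact on a structureless cohort — holds
only approximately there.

## Numerical choices and problem sizes

* EM: relative tolerance 1e-6, max 500 iterations, 3 coordinate-descent
  sweeps per M-step; SVD initialisation for single deterministic fits,
  random initialisation for stability restarts.
* k-means: 50 restarts (10 within grid cells), seeded; all derived seeds
  stay below 2³¹.
* Noise floor 0.2 (see above); penalty grid 0.03/0.1/0.2.
* Tests and the acceptance script run at 150–200 tumours and 1200–2000
  genes, with 20 replicate cohorts for selection consistency, 500
  resampling replicates for logrank calibration and R = 200 for the
  signature null — sizes chosen to exercise the asymptotics the methods
  rely on while keeping a full run in minutes on one CPU.

## Known limitations

Gaussian treatment of integer CN states; nearest-centroid transfer assumes
the validation cohort shares the training feature scales after
standardization; the elbow rule's 5% band is a convention (sensible on the
stability-weighted variance-explained scale, but not adaptive); the
signature-scoring rule is a documented stand-in; and hazards are
exponential, so no late-crossing survival curves are generated or tested.
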