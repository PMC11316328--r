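---
title: "Methods: kernels, samplers, networks and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernels, samplers, networks and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements and of the choices that were genuinely open when it was built.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Genomic prediction regresses phenotypes of a diversity panel on
genome-wide markers and predicts unphenotyped accessions. The package's
organizing question is whether structural variants — transposon insertion
polymorphisms (MITE-DTX and RLX-RIX), deletions, duplications and
inversions, coded 0/1 for absence/presence — improve prediction over SNPs
alone, and whether SNPs in strong linkage disequilibrium with SVs can act
as their proxies. Six marker classes are carried through every stage:
`SNP, MITE-DTX, RLX-RIX, DEL, DUP, INV`.

## Relationship kernels

The additive kernel follows VanRaden: `K = ZZ' / (2 Σ_j p_j(1-p_j))` with
`Z = M - 2p`. For SV columns the same formula is applied to the 0/1
coding, with `p` defined as half the mean dosage throughout, so one
formula serves all classes and the centering always removes the column
mean. This uniform treatment was an open choice (presence/absence markers
have no heterozygote), made for simplicity and documented here; an
alternative haploid-specific denominator would rescale the kernel without
changing its eigenvectors.

Dominance uses the Vitezica coding (`-2p²`, `2pq`, `-2q²` for genotypes
0/1/2; `D = HH'/Σ(2p_jq_j)²`) and is deliberately undefined for SV
classes. The epistatic kernel is the Hadamard square `A ⊙ A`, left
unnormalized by default (a `normalize` flag divides by the mean diagonal).
Dominance and epistasis enter only the SNP-based input strategies; the
kernels are computed on the fold-selected marker set, with the function
surface allowing any other set.

Allele frequencies are always estimated on training accessions and reused
for test rows — test genotypes may enter a kernel (standard in genomic
prediction), test *phenotypes* never influence any fitted quantity.

Kernel principal components are eigenvector columns scaled by the square
root of their eigenvalue, negatives clamped to zero. The retained count
defaults to the smallest set explaining 95% of the trace — the source
study does not state its count, so it is exposed as `var_explained` /
`n_components` and recorded in run metadata.

## Bayesian samplers

`fit_rkhs()` is a Gibbs sampler for `y = μ + Σ_k g_k + e`,
`g_k ~ N(0, K_k σ²_k)`. Each kernel is eigendecomposed once; effects are
sampled componentwise in the eigenbasis, where the conditional posterior
is independent Gaussian. Eigenvalues below `1e-10` of the maximum are
dropped. Variance components get scaled-inverse-χ² updates with prior
degrees of freedom 5; the prior scales are set so that the prior modes
split 50% of the phenotypic variance equally across the genetic terms,
with 50% for the residual — the documented default heuristic of the
reference Bayesian regression software, re-derived here rather than
imported. A fixed-variance mode freezes the variance components so the
sampler can be checked against the closed-form ridge/BLUP posterior mean
`K(K + λI)^{-1}y`, and `fit_intercept = FALSE` removes the general mean
for exact comparison on centered data.

`fit_bayesc()` implements the spike-and-slab marker regression: each
standardized marker has a common-variance effect with probability π and
zero effect otherwise, `π ~ Beta` parameterized by prior counts `p₀ = 5`
and prior mean `π₀ = 0.01`. Inclusion odds integrate the effect out
analytically. The per-marker sweep is C++ (Rcpp) because it is a tight
`O(np)` loop per iteration; all other updates are vectorized R. The
effect-variance hyperprior is not stated in the source design beyond
"defaults", so the same df-5, R²-based scale heuristic is used, with the
prior mode of the total marker variance at 50% of the phenotypic variance
spread over `p·π₀` expected effects.

Binary traits use Albert–Chib probit augmentation: a latent liability
with threshold 0 and residual variance fixed at 1 for identifiability.
Predicted class probabilities are the normal CDF of the posterior-mean
liability. Phenotype classes `{1,2}` map internally to `{0,1}` (class 2
is the success level); the mapping is recorded in every loss report.

Masked phenotypes (the prediction targets) are handled by per-sweep
Gaussian imputation in `fit_rkhs` (data augmentation) and by exclusion
from the likelihood in `fit_bayesc`; both report posterior-mean
predictions for the masked rows only, and `predict()` refuses unmasked
rows because those would be in-sample values.

Chain settings: the study-scale default is 100,000 iterations, burn-in
500, thinning 5 (`mcmc_settings()`); unit tests and smoke runs use
`test_mcmc_settings()` (5,000 iterations). Both are plain configuration
objects — nothing in the samplers depends on which is passed.

## Marker selection and LD tagging

Marker ranking is a fold-internal single-marker linear regression; binary
traits are regressed on their 0/1 codes (a ranking device, not
inference). The top-k selection (study value k = 10,000) pools p-values
across the requested classes; ties break by |t| then marker id, making
the selection invariant to marker column order. Markers monomorphic
inside a fold are flagged and excluded rather than erroring — inevitable
under subsampling. Pooled ranking may select zero markers from a class;
this is logged, not corrected.

LD between SNPs and SVs is the squared Pearson correlation of dosages.
The genotype-likelihood machinery of the original software stack is not
reproduced: genotypes here are hard calls, for which the dosage r² is the
standard estimator. A SNP tags an SV at `r² ≥ 0.8`. An optional basepair
window bounds the O(#SNP·#SV) scan; at the package's panel sizes no
window is needed.

## Networks

The network module is self-contained (dense, 1-D convolution,
max-pooling, flatten, dropout layers with reverse-mode gradients) because
the hyperparameter grid itself is part of what the package studies:
first-layer units/filters {16, 38, 64, 128}; hidden dense layers 0–3
(MLP) or 1–3 (CNN); hidden units {2, 4, 8, 16}; activations relu/tanh/
linear; optimizers Adam/RMSprop/SGD (learning rates 0.001/0.001/0.01, the
common library defaults); dropout {0, 0.05, …, 0.3}; L1/L2 weights
{0.001, 0.01, 0.1}, with 0 meaning the regularizer is absent. Penalties
attach to hidden dense layers; dropout sits before the 1-unit output
(linear head + MSE for quantitative traits, sigmoid head + binary
cross-entropy for binary). Gradients are verified against finite
differences in the test suite, and a linear MLP must reach the OLS loss.

CNN geometry is not part of the stated grid, so kernel width 3, stride 1,
max-pool width 2 (stride = width) are configuration defaults, exposed and
recorded. Markers feed CNNs ordered by (chromosome, position); principal
components never feed CNNs (they have no spatial meaning). Dosage inputs
are standardized per column on training rows; PC inputs are used as-is.

The multi-input architecture gives each of the six per-class PC blocks
its own dense branch, concatenates, and shares the trunk. Missing classes
are an error for this architecture — a panel without all six classes
cannot use it, and the experiment runner logs that cell as failed rather
than silently repairing it.

Hyperparameter search is successive halving: sample n configurations,
train each for a small epoch budget, keep the top half by validation
loss, multiply the budget, repeat to one survivor, then retrain the
survivor with the full budget. This implements the algorithmic idea of
adaptive resource allocation with early stopping; it does not clone any
specific library's bracket schedule. Epoch budgets, batch size (32) and
patience (10) are configuration, not claims about the source study, which
leaves them unstated.

## Cross-validation and the experiment runner

Two schemes: random k-fold (default 10) and across-population holdout
(test = the distant ARO/ADM-style groups, train = the three large
groups). Network fits additionally split 20% off the training set
(floor(0.2·n) validation rows) for tuning and early stopping; Bayesian
fits use the full training set — so both see identical test sets but
different training subsets, mirroring the study design this package
re-implements.

Per fold, `run_experiment()` recomputes imputation means, allele
frequencies, standardization statistics, GWAS ranking and LD pairs on
training rows only. A taint test in the suite perturbs test-fold
phenotypes and asserts that no selection or scan statistic changes.
Failed cells (e.g. multi-input without six classes, an empty linked-SNP
set) are reported with `NA` loss and the error message — report
completeness is #traits × #folds × #cells. The minimum-loss summary
reduces the table to the best (model, strategy) per trait × scheme.

One master seed fans out to folds, simulator, samplers and network
initialisation through `derive_seed(master, label)`, so a whole
experiment is reproducible from one integer and the derivation is
recorded.

## The synthetic generator: what it emulates, what it does not

`simulate_population()` draws group allele frequencies from the
Balding–Nichols model — for ancestral frequency p and divergence F, group
frequencies are `Beta(p(1-F)/F, (1-p)(1-F)/F)` — giving a single-knob
control of population structure. Defaults emulate the motivating panel:
five groups sized 451/166/75/17/29 (total 738), with the two small
holdout groups at twice the training-group F (they stand in for groups
that are "not phylogenetically close" to the training set). The default
marker panel (2000 SNPs, 450/190/650/220/70 SVs) keeps the class
proportions of the genome-wide panel at roughly 1/115 scale; tests use
smaller panels still, chosen to run in seconds.

SV–SNP linkage is planted, not emergent: a linked SV column is a copy of
its partner SNP column with flip noise whose rate is solved by bisection
to hit the target dosage r², and partner SNPs are drawn fully homozygous
(0/2) — defensible for a predominantly selfing crop and necessary for a
target of r² = 1 to be attainable exactly. Draws are rejected and retried
until the realized r² is within ±0.05 of target.

`simulate_phenotypes()` rescales each class's additive component so its
realized sample variance equals the requested share exactly, and
orthogonalizes the environmental noise against the genetic value so the
realized heritability equals the target exactly. Dominance (heterozygote
indicators) and additive×additive epistasis (products of centered causal
dosages) take stated fractions of the genetic variance. Binary traits
threshold the latent liability (class 2 above the threshold).

What the generator does **not** emulate: coalescent-realistic LD decay
along chromosomes (marker positions are scattered uniformly; only planted
pairs are in LD), recombination maps, genotyping or sequencing error, and
the empirical frequency spectra of real SV classes. Consequently, a
passing pipeline demonstrates correctness of the statistical machinery
and the qualitative reproducibility of the design's contrasts — not that
any particular real-data loss value would be reproduced.

## Numerical choices

* Kernels are symmetrized (`(K + K')/2`) on construction; PSD is enforced
  up to `-1e-8·λ_max`; eigenvalues below `1e-10·λ_max` are dropped in the
  samplers and clamped to zero in PC scores.
* The MAF filter removes markers with folded frequency `≤ 0.01` (strict,
  matching the stated rule) and missing rate `> 0.01`, with missingness
  checked first in the removal log. Whether SV filtering should use
  presence or folded frequency was unstated; folded `min(f, 1-f)` is used
  and flagged.
* Mean imputation: SNP columns keep real-valued means; SV columns round
  half-up to {0,1}. This replaces haplotype-based imputation by design —
  it removes an external tool while keeping the train-only leakage
  discipline; the cost is that imputed SNP dosages are no longer integers
  (the PLINK writer therefore refuses unrounded matrices).
* The log transform for time-to-flowering-style traits defaults to the
  natural log (the base was unstated; monotone equivalence), with
  `log_base` exposed.
* Truncated-normal draws use inverse-CDF sampling with the uniform
  clamped to `[1e-12, 1-1e-12]` to survive deep-tail conditioning.
* Cross-entropy probabilities are clipped to `[1e-12, 1-1e-12]`.
* k-fold sizes are `floor(n/k)` or `ceiling(n/k)` via shuffled
  round-robin assignment; the inner validation share is `floor(0.2·n)`.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own desk-scale study conditions: oracle
equivalence at n = 200 (RKHS, 20,000 sweeps) and n = 150/p = 60 (BayesC
ridge mode); variance partitioning at n = 400, h² = 0.6, six kernels of
250 markers each, with the reported estimate the mean of three
independent replicates (panel + trait + chain) — a single replicate's
attribution noise from correlated class kernels is averaged out, which is
also why the recovery tolerance (±0.15 per share) is honest rather than
generous; BayesC recovery at n = 300, p = 1000, 20 causal markers with
effect magnitudes in [0.8, 1.2] (bounded away from zero — the design
calls for large effects); the end-to-end contrast on ten seeded panels of
n = 300 with 60% of causal variance on SV classes, and the scheme
contrast on eight panels with distant holdout groups (F three times the
training groups' 0.12). These sizes keep the full suite under a few
minutes on one CPU while leaving each check statistically meaningful.

## Known limitations

* The RKHS sampler shares one residual variance across kernel terms (the
  three-kernel additive/dominance/epistasis models assume a single
  residual; the alternative was unstated in the source design).
* Variance-share attribution across six class kernels is only weakly
  identified when classes share population structure and marker counts
  are large relative to n — the kernels converge to the common structure
  matrix. This is a property of the model, not the sampler; the
  acceptance design averages replicates rather than pretending otherwise.
* BayesC assumes standardizable (non-constant) marker columns; the
  experiment runner drops fold-constant columns before fitting.
* The network module is CPU-only and intended for the desk-scale panels
  of this package; it is not a general deep-learning framework.
* `predict()` on Bayesian fits returns posterior summaries for masked
  rows only; refitting is required for new accessions (no out-of-model
  kernel extension).
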