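---
title: "Genomic prediction for single-cross hybrids in multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for single-cross hybrids in multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgp)
library(dplyr)
```

## The problem

Maize breeding programs evaluate hundreds of single-cross hybrids in
multi-environment trials (MET): the same genotypes grown at several
location-by-year combinations, often under contrasting water regimes. Trials
are expensive and seed is scarce, so designs are sparse — many hybrids are
never observed in some environments, and newly made crosses are not observed
at all. Genomic prediction fills those gaps: marker data on the parental
inbred lines, plus phenotypes on related hybrids, predict the performance of
untested hybrid-by-environment combinations.

`metgp` implements this workflow end to end — a two-stage statistical
analysis with additive and dominance GBLUP across correlated environments,
tree-ensemble predictors as a machine-learning alternative, and the CV1/CV2
validation designs used to benchmark both — together with a synthetic-data
generator that reproduces the assumed data structure, so that every stage is
testable without any external dataset.

## Stage 1: per-trial adjusted means

Each trial (one environment) is analysed separately with a fixed-effects
model

$$y = 1\mu + X_1 r + X_2 s + X_3 h + e, \qquad e \sim N(0, I\sigma^2_e),$$

where $r$, $s$ and $h$ are replicate, set and hybrid effects. The adjusted
hybrid mean (eBLUE) is the hybrid's estimated marginal mean under
sum-to-zero constraints on replicate and set effects. Two properties anchor
the implementation: in a balanced complete design the eBLUE equals the raw
hybrid mean, and a constant shift applied to one replicate changes no hybrid
contrast. Because hybrids are nested in sets, set and hybrid columns are
partially aliased; the marginal mean is an estimable function and does not
depend on which aliased columns the fit drops.

Outlying adjusted means are removed per environment and trait with the
1.5-interquartile-range rule, using linear-interpolation quartiles
(`stats::quantile()` type 7) and closed fences, in a single pass: the fences
are computed once from the incoming values. Whether such screening should use
plot values or adjusted means, and which quantile convention applies, is
rarely stated in trial reports; both the value column and the grouping are
arguments, and the single-pass convention was chosen for determinism (the rule
applied repeatedly to its own output could otherwise cascade).

## Genotypes and kernels

Parental inbred lines are screened with the usual sequencing-panel rules
(minor allele frequency at least 5%, at most 20% missing, at most 5%
heterozygous calls — heterozygosity in an inbred is mostly technical error).
Missing calls are imputed by the per-marker mode (ties toward the lower
dosage; inbreds only receive homozygous values), a deliberately simple rule:
imputation accuracy feeds no downstream contract here, and haplotype-based
imputation belongs to specialised tools. Residual heterozygous calls are
forced to the marker's modal homozygote so hybrid genotypes can be inferred
deterministically as parental averages: a single cross of homozygous parents
has dosage $(m_{line} + m_{tester})/2 \in \{0, 1, 2\}$.

Relationship matrices follow the standard additive and dominance codings.
With allele frequencies $p_k$ estimated from the hybrid matrix itself,

$$A = \frac{W W'}{2\sum_k p_k(1-p_k)}, \qquad
  D = \frac{H H'}{\sum_k (2 p_k q_k)^2},$$

where $W$ centers dosages by $2p_k$ and $H$ codes dosages 0, 1, 2 as
$-2p_k^2$, $2p_kq_k$, $-2q_k^2$. Estimating frequencies from the hybrids
(rather than the parents) makes every row of $A$ sum to zero exactly — a
cheap, sharp invariant — and describes relationships in the population whose
covariance the kernels model. Both matrices are Gram matrices, hence positive
semidefinite; realized kernels can still be numerically singular, so a ridge
(default $10^{-6} I$) is added before any factorization.

## Stage 2: multi-environment GBLUP

The joint model over the $p \times q$ hybrid-by-environment adjusted means
(environment-major ordering) is

$$\bar y = Xb + Z_1 u_a + Z_2 u_d + e,$$

$$u_a \sim N\!\left(0, [I_q\sigma^2_{u_a} + \rho_a(J_q - I_q)] \otimes A\right),
\quad
u_d \sim N\!\left(0, [I_q\sigma^2_{u_d} + \rho_d(J_q - I_q)] \otimes D\right),$$

with environment means fixed and i.i.d. residuals. The compound-symmetry
(CS) structure assumes one common genetic correlation between any two
environments — a strong but parsimonious way to let prediction borrow
strength across environments; it is positive definite iff
$\rho \in (-1/(q-1), 1)$. Dropping $u_d$ gives the additive-only model;
restricting to one environment ($q = 1$, no correlations) gives the
within-environment fits used for per-environment genetic parameters.

### REML

Variance components maximize the restricted log-likelihood
$-\frac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ over transformed parameters:
log variances and a scaled logistic map of each correlation onto its open
interval. The optimizer is bounded quasi-Newton (L-BFGS-B) with analytic
gradients ($\partial \ell / \partial\theta_i = -\frac12[\mathrm{tr}(P\,
\partial V) - y'P\,\partial V P y]$), verified against numerical
differentiation in the test suite. Starting values split the phenotypic
variance equally across the included components with correlations at 0.3;
on failure, up to two jittered restarts are tried, and parameters that end
on the optimizer's box are flagged rather than clipped.

Two exact evaluation paths share one interface:

* **complete grids** — both CS structures share the eigenbasis whose first
  vector is constant, so rotating the environment dimension into that basis
  splits $V$ into $q$ independent $p \times p$ blocks
  $\lambda_a^{(m)} A + \lambda_d^{(m)} D + \sigma^2_e I$. A fit with
  $p = 300$, $q = 4$ takes about a second;
* **incomplete grids** (masked validation cells) — missing cells are deleted
  from rows/columns of $V$; the four Kronecker pieces
  $(I \otimes A)$, $((J-I) \otimes A)$ and their dominance counterparts are
  precomputed once, so each likelihood evaluation is scalar combinations
  plus one Cholesky factorization.

A subtlety worth recording: with a *structureless* kernel ($A = I$), the
additive and residual variances are not jointly identifiable under CS (the
likelihood is flat along $\sigma^2_{u_a} + \sigma^2_e$ at $\rho = 0$). Null
checks therefore use realized genomic kernels, whose varying off-diagonal
relatedness makes $\sigma^2_{u_a}$ identifiable.

### Inference and prediction

Nested models are compared by `LRT = 2(logL_c − logL_r)` against a
chi-square with one degree of freedom at the 5% level. For a variance
component the null value sits on the boundary of the parameter space, where
a 50:50 mixture of chi-squares would be the asymptotically correct
reference; the plain one-df convention is retained deliberately, matching
long-standing variance-component practice, and is slightly conservative.

Genetic parameters are the variance ratios
$h^2 = \sigma^2_{u_a}/(\sigma^2_{u_a}+\sigma^2_{u_d}+\sigma^2_e)$,
$d^2 = \sigma^2_{u_d}/(\cdot)$, $H^2 = h^2 + d^2$. The bundled reference
table of published estimates for a 265-hybrid maize drought-tolerance
program (`met_reference_varcomp()`) lets this arithmetic be checked against
an independent source; all cells agree within $\pm 0.01$, with two cells off
at the second decimal that are consistent with truncation rather than
rounding in the source (one residual variance in that table is printed with
a decimal comma and is read as 1.64).

Predictions for arbitrary cells are conditional means under the fitted
joint Gaussian: $\hat y_{ij} = \hat b_j + \mathrm{Cov}(u_{ij}, y_{obs})
V_{obs}^{-1}(y_{obs} - X\hat b)$ with $\hat b$ by generalized least squares.
The test suite pins this against a brute-force conditional-mean oracle on
small instances and against the textbook single-kernel GBLUP identity for
$q = 1$.

## Tree ensembles

Bagging, random forest and gradient boosting predict the adjusted mean of a
cell from the hybrid's SNP dosages plus one-hot location and year
indicators, so a single model serves every environment of a regime group.
Hyperparameters are fixed, not tuned: 500 trees for bagging and random
forest, $m_{try} = \lfloor p/3 \rfloor$ (counting all predictor columns,
environment indicators included), and for boosting 250 trees, learning rate
0.1, depth 3. Bagging and random forest are fitted through the
`randomForest` machinery (bagging is exactly the $m_{try} = p$ special
case, so the equivalence is structural, and the averaging rule is asserted
against the per-tree predictions); boosting is a shrinkage loop over
depth-limited `rpart` trees fitted to the current residuals around a
training-mean baseline — a pure accumulation rule omits the baseline, but
that only shifts predictions by a constant. No row subsampling is used.
Trees split by variance reduction with minimum node size 5 and no pruning
for bagging/random forest. Because each boosting tree is a least-squares
projection of the current residuals, the training error is provably
non-increasing in the number of trees for learning rates in $(0, 1]$ — the
suite checks the whole curve.

## Validation design

Hybrids are dealt into $k = 5$ folds, stratified by cross type (dent×dent,
dent×flint, flint×flint, C×dent, C×flint) with round-robin assignment after
a seeded within-stratum shuffle, so fold sizes within a stratum differ by at
most one (265 hybrids in one stratum give five folds of 53). Three masking
scenarios per fold:

* **CV1** — the validation hybrids lose all $q$ environments (new crosses);
* **CV2-50%** — each loses a random half of its environments;
* **CV2-25%** — each loses a random quarter (one of four).

Masked environments are drawn independently per hybrid, uniformly over
subsets of the required size — the sparse patterns seen in practice vary,
and the uniform law is the least-informative choice. Internally a random
permutation of the environments is drawn per validation hybrid and each
scenario masks a prefix of it, so within a repeat the masks *nest* across
scenarios (a hybrid's CV2-25% masked cell is among its CV2-50% masked
cells). Nesting leaves every scenario's marginal masking law untouched but
pairs scenario comparisons, in the spirit of common random numbers — the
difference between two scenarios is then driven by the extra observed
records, not by which cells happened to be masked. Folds and masks are
generated once per repeat and shared across methods so method comparisons
are paired too.

Ability is the Pearson correlation between adjusted means and predictions
over masked cells, per environment. By default the masked cells of all five
folds within a repeat are pooled before correlating: every hybrid is held
out exactly once per repeat, so this correlates the assembled
cross-validated predictions with the observed means — the way such
benchmarks are usually scored. Per-fold scoring is available
(`score_by = "fold"`), but at moderate hybrid counts a per-fold,
per-environment correlation rests on very few cells, which is noisy and —
because the small-sample bias of the Pearson estimate pulls toward zero
more strongly for smaller cell counts — systematically understates the
scenarios that mask fewer cells. The reported standard error divides the
standard deviation of the ability values by the square root of the number
of repeats (a convention, exposed as an argument, since ability plots
rarely define their error bars). GBLUP fits inside the loop may warm-start
from the full-data variance components — a numerical head start only, which
does not change the optimum and is switchable off.

## The synthetic generator

The generator is the package's study design. Defaults describe a tropical
maize testcross program under water stress: 188 inbred lines in three
heterotic groups (85 dent, 86 flint, 17 unrelated) crossed to two testers
for 265 hybrids; four environments (two locations by two years) with
intercepts 3.49, 2.86, 3.34, 4.93 t/ha; variance components
$\sigma^2_{u_a} = 0.6$, $\sigma^2_{u_d} = 0.3$, $\sigma^2_e = 0.8$ with
$\rho_a = 0.35$, $\rho_d = 0.8$ — magnitudes typical of grain yield under
drought stress, where dominance carries a large share of the genetic
variance and environment ranking is inconsistent; two to three replicates
per trial and six sets.

Parents are fully homozygous; each marker's base allele frequency is drawn
from the configured MAF range and perturbed per heterotic group on the logit
scale with standard deviation `group_divergence`, so groups diverge smoothly
while allele-substitution effects stay common to all groups. Marker effects
are i.i.d. Gaussian per marker with the CS correlation across environments,
scaled through the *same* centered designs the kernels use, so the
covariance of the simulated genetic values is exactly
$\sigma^2 \, CS(\rho) \otimes K$ with $K$ the realized kernel — the fitted
model is the exact generative model, which is what parameter-recovery
checks require. Two record-level generators sit on top: plot records
(environment intercept + replicate/set shifts + genetic value + noise) to
exercise stage 1, and cell-level adjusted means to exercise stage 2
directly.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: linkage disequilibrium and genetic maps (markers
are independent; LD affects kernel quality, not the inferential contracts
tested here), selection history and pedigree depth, spatial field trend,
genotype-by-management interaction beyond the CS correlation, and
non-Gaussian residuals. Replicate and set effects default to zero because
their real-world magnitudes are rarely reported; they are configurable so
the stage-1 adjustment is genuinely exercised.

## Numerical choices and problem sizes

Tolerances: optimizer relative tolerance $10^{-8}$ by default (relaxed to
$10^{-7}$ inside cross-validation loops), kernel ridge $10^{-6}$, LRT
negativity tolerance $10^{-6}$. Ties in imputation and in the modal
homozygote go to the lower dosage. Record ordering is fixed everywhere as
environment-major, hybrid-minor; all Kronecker assembly and masking index
from that single convention.

The test suite exercises parameter recovery at 300 hybrids by four
environments over 20 simulated datasets, and the cross-validation ordering
checks (CV2-25% ≥ CV2-50% ≥ CV1 for GBLUP-AD, and GBLUP-AD ≥ GBLUP-A in
overall mean, each in a majority of 20 seeds) at 120 hybrids with two
repeats of five folds — sizes chosen so the whole suite runs on a laptop in minutes
while keeping the Monte-Carlo bounds comfortably away from their thresholds.
At these sizes per-environment fold abilities are computed from few cells
and are individually noisy; the checks therefore compare scenario means, as
ability summaries do in practice.

## Known limitations

* The CS correlation is a single number for all environment pairs;
  factor-analytic or unstructured G×E covariances are out of scope.
* Stage 1 is fixed-effects only (no spatial correction, no mixed stage 1).
* The LRT reference deliberately ignores the boundary issue (see above).
* Mode imputation is not a substitute for haplotype imputation when
  imputation accuracy itself matters.
* Tree ensembles use fixed published-style hyperparameters; there is no
  tuning machinery.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)          # 265 hybrids, 4 environments, GY-like
sim <- simulate_met(cfg)
eb  <- compute_eblues(sim$plots) |> remove_outliers()
A   <- grm_additive(sim$hybrids)
D   <- grm_dominance(sim$hybrids)

fit <- reml_fit(sim$cells, A, D, model = "AD")
tidy(fit)
genetic_params(fit)

ab <- run_cv(sim$cells, A = A, D = D,
             methods = c("gblup_a", "gblup_ad"),
             scenarios = c("CV1", "CV2_50", "CV2_25"),
             repeats = 2, strata = setNames(sim$crosses$cross_group,
                                            sim$crosses$hybrid))
autoplot(ab)
```
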