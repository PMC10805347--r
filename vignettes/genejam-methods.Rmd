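---
title: "Methods: clustering and jointly modelling correlated traits via polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering and jointly modelling correlated traits via polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genejam)
```

## The problem

A multivariate GWAS measures q quantitative traits on the same N
individuals. Traits are often correlated — partly because pleiotropic
variants affect several of them, partly because individuals share
environments. Modelling each trait separately by ordinary least squares
(OLS) is unbiased but statistically inefficient when residuals are
correlated across traits, while a fully parameterized multi-trait mixed
model needs O(q^2) covariance parameters and scales poorly in q.

genejam takes a middle road. Each trait l gets one polygenic score (PGS)
z_l, a scalar genetic predictor. If two traits share genetic architecture,
their scores are correlated; conversely, under a multivariate-Gaussian
approximation for the scores, a zero entry (i, j) of the scores' precision
matrix means scores i and j are conditionally independent given the rest.
Estimating a *sparse* precision matrix therefore yields a graph over traits
whose connected components are clusters of traits sharing genetic
characteristics — and only within those clusters do we allow residual
correlation when fitting the per-trait regressions jointly.

## The model

For individual i, stack the q trait values row-wise so that
Y-vec = Z-design B + E with E ~ N(0, I_N ⊗ R): the same q×q
within-individual residual covariance R repeats for each of the N
independent individuals. Each trait's mean model is an intercept plus its
own score, b_l = (ξ_l, β_l), so B has 2q entries. The vectorization
convention is row-wise (trait index fastest); with the column-wise
convention the Kronecker factors silently swap order, so the package fixes
and documents row-wise throughout.

The procedure (implemented by `genejam()`) is:

1. **Scores** (`marginal_weights()`, `compute_scores()`): for every SNP j
   and trait l, the slope of the univariate regression of y_l on x_j alone,
   computed in closed form from sample moments; the score is
   z_il = Σ_j x_ij ŵ_jl. The marginal intercepts are estimated (and kept
   for diagnostics) but deliberately not added to the score: the score is a
   weighted allele-count sum, and any location shift is absorbed by the
   intercept of the downstream regression. SNPs with zero variance get
   weight 0 with a warning.
2. **Graph** (`standardize_scores()`, `graphical_lasso()`,
   `precision_adjacency()`, `trait_components()`): columns of Z are centred
   and scaled to unit variance, so their covariance and correlation matrix
   S coincide; the graphical lasso maximizes
   log det(P) − tr(SP) − ρ‖P‖₁ over positive-definite P; entries of P
   with |P_ij| > 1e-8 define edges; connected components define clusters.
3. **Fit** (`fgls_fit()`): starting from per-trait OLS, alternate between
   estimating R from the current residuals — sample covariance within each
   component, exact zeros across components — and re-estimating B by
   generalized least squares under I_N ⊗ R, to convergence.
4. **Tuning** (`rho_path()`, `average_se()`): repeat 2–3 along a penalty
   grid and select the ρ minimizing the average standard error of the
   clustered slopes.

## Numerical choices

**Graphical-lasso solver.** The `glasso`-style blockwise coordinate descent
is implemented in the package: each column of the working covariance W is
updated by solving a lasso subproblem by coordinate descent; sweeps stop
when the mean absolute change of W's off-diagonal falls below
1e-6 × mean |off-diagonal of S|, with a cap of 200 sweeps (non-convergence
is an error naming ρ). The ℓ1 penalty is applied to off-diagonal entries
only (`penalize_diagonal = FALSE` by default): the downstream consumer is
the sparsity pattern, which is essentially unchanged by diagonal
penalization, and the off-diagonal-only convention admits clean closed-form
checks — at ρ = 0 the solution is S⁻¹ exactly, for
ρ ≥ max |S_ij| it is diag(1/S_ii), and for q = 2 the working covariance is
the soft-thresholded S. Tests verify all three plus the KKT subgradient
conditions with an independent checker.

**Penalty grid.** From the minimum absolute off-diagonal of S to the
maximum absolute column sum of S, 50 linearly spaced values by default
(log spacing available). Both endpoints adapt to the data, so the path
always spans near-dense to fully disconnected graphs. A left endpoint of
exactly 0 is kept only when S is invertible (otherwise nudged to 1e-4,
since the unpenalized problem is ill-posed for singular S). The path is
evaluated in increasing order and stops early at the first ρ whose graph
has no edges: a positive-definite precision estimate can never be literally
zero, so "no off-diagonal structure" is the operative reading, and larger
penalties can only stay empty.

**Tuning criterion.** Singleton traits are fitted by plain OLS at every
penalty, so they carry no information about the clustering; the criterion
averages the slope standard errors over traits in components of size ≥ 2
and is undefined (NA) when there are none. The selected ρ minimizes this
average; ties break toward the *smaller* ρ, i.e. toward denser clustering —
erring on the side of complexity costs efficiency, not consistency, while
missing a true cluster forfeits the joint-modelling gain. If the criterion
is undefined along the whole path, the fit falls back to per-trait OLS with
a message. The standard-error vector has one entry per trait: the slope SE
(the slope carries the genetic signal; a config switch in the fit object's
`vcov_diag` exposes intercept variances too). The textbook GLS expression
diag((Z'Ω⁻¹Z)⁻¹) is a variance, so the package reports its square root.

**FGLS details.** Residual covariances use denominator N − 1. The
Nq × Nq covariance is never materialized: each cluster g is an independent
seemingly-unrelated-regressions system whose normal matrix is assembled
from Rg⁻¹[l, l'] × crossprod([1, z_l], [1, z_l']). Iteration stops when the
largest coefficient change relative to the largest coefficient magnitude
falls below 1e-6 (max 100 iterations; non-convergence returns the last
iterate with `converged = FALSE` and a warning). A residual covariance
block with condition number above 1e10 receives a relative ridge of 1e-8 on
its diagonal — path endpoints can throw nearly all traits into one cluster,
and a warning is preferable to a hard failure there. A component larger
than N − 1 traits is an error (its covariance cannot be full rank).
Degenerate (zero-variance) score columns are excluded from graph
estimation, forced to be singletons, and fitted intercept-only.

## The simulator

`sim_design()` / `simulate_study()` generate data under the infinitesimal
model: genotypes are independent SNPs x_ij ~ Binomial(2, π) (Hardy–Weinberg
frequencies π², 2π(1−π), (1−π)²; π fixed at 0.3 by default or drawn
per-SNP from a range), per-SNP effect rows C_j ~ N(0, Σ_C), environmental
rows E_i ~ N(0, Σ_E), and Y = XC + E. With unit environmental variance the
targets translate to V_A,l = h²_l/(1 − h²_l), per-SNP effect variance
Σ_C[l,l] = V_A,l/(p·V(X)), and a phenotypic covariance
ρ√(V_P,l V_P,l') between the designated trait pair that is split between a
genetic part (1 − τ_E, carried by Σ_C) and an environmental part (τ_E,
carried by Σ_E). Both implied correlations must lie in [−1, 1], which
bounds the feasible (h², ρ, τ_E) region; infeasible designs error with the
violated constraint. The factor p in the effect variance keeps realized
heritability independent of the SNP count.

Scores are built in two stages, mimicking weights obtained from an
unrelated GWAS: stage 1 simulates a training sample and estimates the
marginal weights on it; stage 2 simulates an independent genotype sample
with the same allele frequencies and the *same* effect matrix C, computes
Z = XŴ with the stage-1 weights, and draws fresh environmental noise for
the analysis traits. The literal reading — stage 2 reuses stage-1 C — is
adopted: the clusters to be recovered are a property of the genetic
architecture, which does not change between cohorts.

Two architectures are provided: `pair` (traits 1–2 heritable and
correlated, the rest null; the true graph has one edge) and `all_shared`
(identical effect vectors for all traits, genetic correlation 1; the true
graph is complete).

What the simulator does *not* emulate: linkage disequilibrium between
SNPs, population structure or relatedness, non-Gaussian traits, and
covariates. Passing tests on these data show the estimation machinery is
correct under the generating model, not that the method is robust to those
real-data features.

## Study conditions and known limitations

The package's Monte-Carlo evaluation (`replicate_study()`, the acceptance
script, and the end-to-end tests) uses q = 10 traits, N = 1000
individuals, p = 2000 SNPs at MAF 0.3 and 25 replicates per design cell —
a desk-scale version of the reference design (which uses p = 10000 and 100
replicates) chosen so a full study grid runs in minutes on one CPU.

Two behaviours of the method at this scale deserve explicit note, because
they are properties of the procedure rather than bugs:

* **Two-stage scores inherit environmental correlation.** Marginal weights
  estimated on a training sample whose traits share environmental
  correlation have cross-trait *correlated estimation noise* (per SNP,
  roughly cov(y_l, y_l')/(N·V(X))), so the resulting scores correlate
  through the full phenotypic covariance, not only its genetic part. The
  pipeline therefore still detects a trait pair whose correlation is
  largely environmental (τ_E large) — it recovers the pair, but for a
  partly non-genetic reason. Truly environment-free scores would require
  training data without the shared-environment structure (e.g. external
  PGSs), which the two-stage design does not provide.
* **Near-tie selection favours density.** When no real clustering signal
  exists (null or very weak designs), the average-SE values along the path
  differ by fractions of a percent, and the reported GLS standard error of
  a k-trait cluster carries a finite-sample downward bias of order k/(2N)
  (inverting an estimated covariance overstates information). The
  tie-break toward smaller ρ then keeps spurious edges more often than
  not. Interpreting a selected clustering on data with little genetic
  signal therefore warrants inspecting `path_diagnostics()` — a flat
  average-SE curve means the clustering is weakly identified.

Per-replicate failures inside `replicate_study()` (e.g. a singular block
at an extreme penalty) are logged and excluded, with the exclusion count
reported, never silently dropped.

## Evaluation metrics

* `rand_index()` compares two adjacency matrices by edge agreement over
  the q(q−1)/2 unordered pairs — the literal adjacency-level Rand index.
  Since an estimated glasso graph need not be transitively closed, a
  `co_membership = TRUE` option compares component co-membership instead;
  the default is the edge-level form.
* `trait_rmse()` is the per-trait root mean squared prediction error.
* `estimated_correlation()` reads the correlation of a trait pair off the
  selected fit's cluster-block residual covariance (structurally 0 across
  components). Note this estimates the *residual* correlation given the
  scores; the more predictive the scores, the further below the phenotypic
  correlation it sits.

## Preprocessing for real genotype tables

`read_genotypes()` validates additive 0/1/2 coding and keeps missing
entries; `impute_family_mean()` replaces a missing genotype by the mean of
that SNP within the individual's family (falling back to the overall SNP
mean when a family has no observed value), leaving imputed values
fractional; `filter_snps()` drops zero-variance SNPs and SNPs with
estimated MAF at or below 1% (strictly-above retained). The order —
impute, then variance filter, then MAF filter — is fixed. PLINK binary
ingestion is out of scope; inputs are delimited text tables.
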