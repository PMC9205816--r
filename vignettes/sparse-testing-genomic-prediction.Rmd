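---
title: "Sparse testing with multi-environment genomic prediction: models and methods"
author: "sparsegp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse testing with multi-environment genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsegp)
```

## The problem

Early-stage yield testing in a plant breeding program faces a fixed
phenotyping budget: a set of candidate lines can either be tested in few
environments with full replication, or spread — *sparsely* — across many
selection environments (SEs), with genomic prediction filling in the
unobserved line-by-environment cells. Whether sparse testing works depends
on how much information flows across environments, which in turn depends on
the genetic correlations between environments and on the genomic (or
pedigree) relationships among lines. `sparsegp` implements the full chain
needed to study and deploy this strategy: a synthetic breeding-data
generator, marker QC and relationship matrices, a multi-environment REML
mixed model with factor-analytic genotype-by-environment (GxE) covariance,
sparse line-allocation designs, and selection-accuracy metrics that mirror
a breeder's advancement decisions.

## The mixed model

The central fitting function `megblup()` models the plot-level phenotype as

$$
y = \mathbf{1}\mu + X_1 b_1 + Z_1 u_1 + Z_2 u_2 + Z_3 u_3 + Z_4 u_4
  + Z_5 u_5 + \varepsilon ,
$$

with a fixed replicate effect $b_1$ and iid random effects for the SE main
effect ($u_1$), trial ($u_3$), replicate within SE and trial ($u_4$) and
incomplete block within replicate ($u_5$), each $u_p \sim N(0,
I\sigma^2_p)$. The term of scientific interest is the line-by-environment
genetic effect

$$
u_2 \sim N\!\left(0,\; G_o \otimes K\right),
\qquad G_o = \Lambda\Lambda^\top + \Psi ,
$$

where $K$ is a genomic ($G$, VanRaden method 1) or pedigree ($A$, tabular
method) relationship matrix over lines and $G_o$ is the $k \times k$
between-environment genetic covariance in factor-analytic (FA) form:
$\Lambda$ holds the environment loadings on $m$ latent factors and $\Psi$
the environment-specific variances. The diagonal of $G_o$ is the additive
genetic variance within each SE; off-diagonals are genetic covariances
between SEs, reported as correlations by `genetic_correlations()`.

Residuals are independent between environments with per-environment
variance $\sigma^2_k$ and, optionally, a separable first-order
autoregressive correlation across field columns and rows within each
environment, $R_k = \sigma^2_k\,[\mathrm{AR1}(\rho_c) \otimes
\mathrm{AR1}(\rho_r)]$. Plot-level heritability per environment is the
variance ratio $h^2_k = \sigma^2_{g_k} / (\sigma^2_{g_k} +
\sigma^2_{\varepsilon_k})$ with $\sigma^2_{g_k} = G_o[k,k]$
(`plot_heritability()`).

Two companions complete the picture. `compute_blues()` refits the model
with the line-by-environment effects as *fixed* — the best linear unbiased
estimates used as reference genotypic values — and `predict()` on a fit
returns the empirical-BLUP genetic effect of every line in the kinship
matrix in every environment, whether phenotyped there or not. A multi-year
variant treats environment-by-year combinations as the environment levels
and nests replicate and block effects within year; a single-environment
variant drops the GxE dimension and uses $\sigma^2_g K$.

### Identifiability and parameterization

$\Lambda$ is identified only up to rotation, so loadings above the diagonal
are fixed at zero and the leading loading of each factor is reported with a
positive sign; $\Psi \ge 0$ and all variances are kept positive through a
log transform. With $m = 1$ and $k = 2$ the FA structure spans every valid
2-environment covariance, which is what makes small-instance comparisons
with an unstructured oracle exact. The FA order defaults to $m = 1$ — the
single-factor structure already captures the "one low-correlation,
low-heritability environment against a correlated majority" pattern typical
of managed SE sets — and can be raised to $m \le k$.

## REML estimation

All likelihood quantities go through the Woodbury identity: with random
effect covariance $D = LL^\top$ the only large factorization per
evaluation is the Cholesky of $I_q + L^\top Z^\top R^{-1} Z L$ in the total
number of random-effect levels $q$, so the cost scales with the number of
lines times environments rather than with the number of plots. The genetic
block of $L$ is assembled as $\mathrm{chol}(G_o)^\top \otimes
\mathrm{chol}(K)^\top$ and multiplied through its Kronecker structure.

Optimization proceeds in two phases:

1. **EM warm-up** (default 8 iterations). Proper REML-EM updates for every
   variance parameter, with the FA block updated by maximizing the M-step
   objective over $(\Lambda, \Psi)$ via the Rubin–Thayer iteration started
   from the current values. Each sweep provably does not decrease the REML
   log-likelihood — the package's test suite checks this monotonicity — and
   moves crude moment-based starting values into the basin of the optimum.
2. **Quasi-Newton polish**: L-BFGS-B on the transformed parameters with
   *analytic* gradients (trace terms are assembled from the same
   factorizations), run to a log-likelihood tolerance of `tol` (default
   1e-8) and restarted once, which clears occasional limited-memory
   line-search stalls at negligible cost.

Spatial autocorrelations are profiled in an outer loop: for each
environment, a coarse grid over $(\rho_c, \rho_r)$ followed by simplex
refinement at the current variance parameters, alternated twice with inner
REML fits. Profiling avoids the boundary instability of joint Newton steps
in $\rho$; the simplex refinement plays the role a one-dimensional
golden-section search would play per coordinate, but handles the
column/row pair jointly.

Variance components shrinking below about $10^{-6}$ of the phenotypic
variance are reported with a boundary flag rather than being pinned exactly
at zero; under a true null the REML genetic variance behaves like a
boundary-censored half-normal, so single realizations may sit a few percent
above zero — the tests assert the median over seeds.

### The balanced fast path

When the data form a complete line-by-environment table with exactly two
replicates, iid residuals, no design variance components and fixed
environment means, `megblup(engine = "auto")` switches to an exact fast
path: plots decompose orthogonally into cell means and within-cell
replicate differences, and rotating the cell-mean matrix by the
eigenvectors of $K$ factorizes the likelihood into $N$ independent
$k$-variate normals whose covariances $s_i G_o + \mathrm{diag}(\sigma^2/2)$
are simultaneously diagonalized. An evaluation then costs a few $k \times
k$ eigen decompositions instead of a $q^3$ Cholesky — about three orders of
magnitude faster at 300 lines — and the test suite verifies that both
engines return identical log-likelihoods and BLUPs to near machine
precision (the orthogonal decomposition has unit Jacobian and the implicit
replicate coding differs from the general engine's sum-to-zero contrast by
a unit-determinant transformation up to a factor 2, absorbed as a
$-\log 2$ constant).

### The validation oracle

`reml_direct()` and `reml_direct_fit()` are a deliberately naive reference
implementation: they build the full $n \times n$ covariance matrix from
the model definition and evaluate or maximize (Nelder–Mead then BFGS from
several neutral starts, log-Cholesky parameterization of an unstructured
$G_o$) the error-contrast normal log-likelihood with dense algebra. They
share no code with the engine; on small instances the engine must agree
with them to about 1e-8 in evaluation and 1e-4/1e-3 in maximized
log-likelihood/components, which the acceptance tests enforce.

## The synthetic-data generator

The generator emulates the architecture of an elite spring-wheat yield
testing stage so every downstream operation is testable without external
data:

* **Population**: founders in linkage equilibrium with allele frequencies
  drawn from `maf_range`; biparental crosses with family sizes drawn
  uniformly from 1–9 (the small-family regime in which individual lines are
  rarely replicated across environments); progeny generated by
  independent-locus Mendelian gamete sampling followed by (default) three
  generations of selfing, approximating the near-homozygosity of
  F4-derived lines. Loci are unlinked: relationship-based prediction needs
  relatedness, not linkage, and no downstream operation depends on LD
  structure.
* **Trial design**: per environment, lines are grouped into trials of 56
  entries plus 4 repeated checks, grown in two replicates with near-equal
  incomplete blocks (default size 7–8) nested in replicate — the nesting
  structure of an alpha-lattice without the formal alpha(0,1)
  construction, which the model does not require. Plots sit on a
  row-by-column grid (15 columns by default, trials stacked in row bands).
* **Phenotypes**: plot value = mean + environment + trial + replicate +
  block effects + genetic value + AR1$\otimes$AR1 spatial noise. Genetic
  values are built mechanistically from `n_qtl` sampled marker effects per
  latent factor, scaled so the factor scores have covariance $K$ across
  lines — i.e. exactly the $G_o \otimes K$ scale of the model — with
  environment-specific deviations added at variance $\Psi$. A
  `direct_mvn` flag instead draws straight from the model distribution,
  for oracle tests. Checks receive fixed true values replicated across
  trials.

Because genetic variances are *per unit kinship*, a line's marginal
variance is $\mathrm{diag}(K) \times \mathrm{diag}(G_o)$; for inbred panels
($\mathrm{diag}(K) \approx 1.9$) the realized plot-level signal is
correspondingly larger than $G_o$ while fitted components remain directly
comparable to the architecture's truth. What the generator does *not*
emulate: linkage disequilibrium and marker ascertainment, genotyping error
and imputation artefacts, selection during line development, and
multi-trait genetic architecture. Passing tests therefore demonstrate
correctness of the machinery and qualitative transfer of the design
findings, not quantitative performance on any real dataset.

`demo_architecture()` freezes the package's canonical six-environment
truth: five environments with pairwise genetic correlations of about
0.67–0.86 and plot heritabilities 0.35–0.6, plus one weakly negatively
correlated environment with $h^2 = 0.18$ — an early-heat-stress analogue —
against unit residual variance.

## Sparse-testing designs

Two allocation schemes split the candidate set across $k$ environments:

* `allocate_nonoverlap()`: a random partition into $k$ sets whose sizes
  differ by at most one (46/47 for 280 lines in six SEs); each set is the
  calibration set of one environment.
* `allocate_overlap()`: `overlap_count()` lines are tested in *every*
  environment and the remainder is split into exactly equal unique sets.
  The overlap count is the smallest $x \ge f \cdot n$ with $(n - x)$
  divisible by $k$ — the rule that reproduces the printed series 28, 58,
  88, 112, 142 overlapping lines and 70, 95, 120, 140, 165 calibration
  lines per SE for $n = 280$, $k = 6$ at 10–50%. Rounding up keeps the
  unique sets exactly equal-sized.

`replicate_plans()` re-randomizes an allocation (30 repeats by default,
seeds derived as `base_seed + i`), and `mask_phenotypes()` splits a plot
table into training records and the masked line-by-environment cells whose
genetic values are to be predicted. Checks sit outside the allocation:
they are phenotyped everywhere and excluded from accuracy sets.
Randomization is simple line-level sampling (a family-stratified option
exists but is off by default, matching the random-allocation design being
emulated).

## Selection metrics

Predictive ability is the Pearson correlation between predicted genetic
effects of the prediction set and reference BLUEs from the full data,
per environment. Selection-intersection accuracy mirrors the advancement
decision: rank lines by a Smith–Hazel index $b = P^{-1} G_o w$ over their
environment-wise GBLUPs, select the top 20%, and measure the proportion
shared with the top 20% selected from full-data GBLUPs. The index's
genetic covariance is the fitted $G_o$; the phenotypic covariance adds the
per-environment residual variance on a line-mean basis ($\sigma^2_k /
n_{\mathrm{rep}}$, configurable) — the standard construction for an index
on entry means. The default economic weights $(0.25, 0.1, 0.3, 0.2, 0.1,
0.05)$ are bound positionally to the sorted environment labels; any
domain-specific correspondence between weights and environments should be
imposed by naming environments accordingly. Ties at the selection cutoff
break by line id, and the selected count is $\lceil f \cdot n \rceil$, so
selections are reproducible.

## The experiment driver

`run_sparse_experiment()` ties everything together: full-data reference
GBLUPs and BLUEs are computed once per kinship matrix (recomputing them per
repeat would return identical values), allocation plans are shared across
kinship matrices so GBLUP/PBLUP comparisons are paired, per-repeat model
failures are recorded and excluded from summaries rather than aborting the
run, and nuisance variance components for the BLUE model are reused from
the full-data BLUP fit (refitting them under the line-fixed model is
supported but costs far more and moves BLUEs negligibly on these designs).
Historical-data augmentation either appends a single historical environment
as an additional correlated environment (with `*`-suffixed label) or a full
prior-year table under the year-nested model; history lines without marker
data enter the kinship as an identity block via
`block_diagonal_kinship()`. `stage_advancement()` compares single- and
multi-environment stages by correlation and top-fraction overlap of a
selection metric, the lens through which relationship-aware GBLUP and
independence-assuming BLUEs are contrasted as advancement criteria.

## Numerical choices and degenerate inputs

* Kinship matrices get a $10^{-6}$ diagonal ridge before factorization
  (`stabilize_kinship()`; an optional 0.99/0.01 identity blend is off by
  default). Clones and duplicated kinship rows are therefore handled, at
  the price of predictions for "twins" agreeing only to about the ridge
  magnitude.
* Missing grid cells under the spatial model use the marginal (selected)
  rows and columns of the full AR1$\otimes$AR1 correlation, not a
  re-normalized one.
* Random terms with fewer than two levels in the data are dropped with a
  message; a rank-deficient fixed structure has aliased columns dropped
  (BLUE cells flagged `NA` when inestimable).
* MAF filtering computes frequencies on non-missing calls; thresholds are
  inclusive so "more than 20% missing" and "less than 5% MAF" are the
  exclusion events. Marker-mean imputation replaces haplotype-based
  imputation: downstream matrices only need completeness, and phasing
  accuracy is irrelevant at this scale.
* In the BLUE model the environment main effect is absorbed by the fixed
  line-by-environment cells (a random environment term would be fully
  confounded and only add boundary noise), and the replicate contrast is
  coded sum-to-zero so estimates stay on the data scale.

## Problem sizes used in tests and the acceptance script

The package's own evaluation uses simulation scales chosen to exercise
every code path while completing in minutes on a single core: oracle
comparisons on instances of about 50 plots; parameter recovery on the
canonical six-environment architecture at 300 lines x 2 replicates over
10 seeds (balanced fast path); and the sparse-testing contrast at 120
lines in six environments with two trials each, 0% vs 50% overlap, 3
allocation repeats (general engine). At these scales the qualitative
findings are stable: predictive ability rises steeply with overlap in
every environment except the weakly correlated one, where it stays near
its within-environment floor, and intersection accuracy of the top-20%
selection rises in step.

## Known limitations

* The FA order is a modelling choice; with $m = 1$ strongly clustered
  correlation structures (two antagonistic groups) are compressed. Raise
  `fa_order` when $k$ is large and correlations are heterogeneous.
* REML surfaces with FA structure can have local optima on small data;
  the EM warm-up plus restart strategy is robust in the tested regimes,
  but multi-start fitting (refitting with `varcomp_init`) is the remedy
  when in doubt.
* The spatial profiler assumes the per-environment grids are modest (a
  dense per-environment correlation is factorized); thousands of plots per
  environment with spatial residuals would need a sparse-precision
  implementation.
* No marker-effect (Bayesian alphabet) models, no heterogeneous-error
  two-stage weighting, and no optimized training-set construction — the
  designs studied here randomize allocation by construction.
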