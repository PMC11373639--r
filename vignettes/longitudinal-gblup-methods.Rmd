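---
title: "Methods: longitudinal GBLUP for tetraploid postharvest traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal GBLUP for tetraploid postharvest traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `blupberry`, the
numerical design of its REML engine, the choices made where the design was
genuinely open, what the synthetic population does and does not emulate, and
the package's known limitations.

## The model

Let `y` collect the phenotypic records of one trait at up to four
postharvest storage time points (1D, 1W, 3W, 7W). The longitudinal mixed
model is

$$y = X_1\beta + X_2 t + X_3 g_1 + Z g_2 + e,$$

* $\beta$: a population mean per time point plus year-of-evaluation
  effects. The per-time intercepts span the column space of the
  postharvest-time effects $t$, so the design absorbs $t$ into $\beta$ and
  stays full rank; the Wald test below recovers the time effect as a
  contrast among the per-time means.
* $g_1$: fixed effects of the check genotypes. In an augmented design the
  unreplicated regular entries are connected across years only through
  these repeated checks, which therefore carry the year-effect information.
  A genotype is a check if and only if it is flagged in the phenotype
  table.
* $g_2$: random genetic effects of regular genotypes, one effect per
  genotype and time point, $g_2 \sim MVN(0, \Sigma_t \otimes G)$.
* $e$: residuals, independent between (genotype, year) units and with
  covariance $\Sigma_e[S_u, S_u]$ across the observed time points $S_u$
  within a unit, i.e. $e \sim MVN(0, \Sigma_e \otimes I)$ at the unit
  level. Fruit measured at different time points comes from different
  clamshell samples of the same harvest, which motivates a within-unit
  residual correlation that the unstructured $\Sigma_e$ can capture.

Technical reps are averaged before modelling: both reps come from the same
field plot, so they are not independent replicates.

Covariance structures for $\Sigma_t$ and $\Sigma_e$:

* `us` — unstructured, $T(T+1)/2$ parameters. The complete model: genetic
  effects specific to each time point, freely correlated.
* `common` (genetic only) — a single effect shared by all time points
  ($\Sigma_t = \sigma^2 J$, rank one, one parameter). Removing the
  genotype-by-time interaction reduces the complete model to exactly this
  structure, so it serves as the null of the interaction likelihood-ratio
  test.
* `indep` — heterogeneous variances, zero covariance ($T$ parameters).
  The "no correlation between time points or residuals" comparison model
  for BIC uses `indep` for both $\Sigma_t$ and $\Sigma_e$.

Traits recorded at a single storage stage (water loss at 7W, pedicel scar
at 1D) are the $T = 1$ special case of the same engine, where all
structures coincide.

## The tetrasomic relationship matrix

With allele dosages $M \in \{0,\dots,4\}$ (autotetraploid) and allele
frequencies $p_j$ estimated as mean dosage over ploidy,

$$W = M - \mathrm{ploidy}\cdot P, \qquad
  G = \frac{WW^\top}{\sum_j \mathrm{ploidy}\, p_j(1-p_j)}.$$

The denominator is the total binomial dosage variance expected under
polysomic Hardy–Weinberg equilibrium, the natural generalization of the
diploid VanRaden scaling (which this formula reproduces at ploidy 2); it
puts the diagonal of $G$ at about 1 in an equilibrium population. Choices:

* Missing dosages are mean-imputed per marker after frequency estimation —
  deterministic and standard; the imputed entries are exactly at the
  centering point, so they contribute nothing to relationships.
* Monomorphic markers (no variation, including constant heterozygotes) are
  excluded; `min_maf` defaults to 0 because dosage panels are usually
  filtered upstream.
* A ridge of $10^{-6}$ on the diagonal keeps $G$ invertible inside the
  mixed model. No pedigree or identity blending is applied beyond the
  ridge.

## REML engine

### Structure exploitation

The restricted likelihood is evaluated exactly without ever forming the
record-level covariance matrix $V$. Records fall into three parts:

1. **Core** — regular genotypes with a single (genotype, year) unit
   observed at the modal time pattern $S$. Two rotations make this block
   diagonal: the eigendecomposition $G_{core} = U D U^\top$ of the
   relationship matrix among core genotypes, and the generalized
   eigendecomposition of $(\Sigma_t[S,S], \Sigma_e[S,S])$, which yields a
   time-basis $\Phi$ with $\Phi^\top \Sigma_e \Phi = I$ and
   $\Phi^\top \Sigma_t \Phi = \Lambda$. In the rotated coordinates the
   covariance is diagonal with entries $1 + d_i \lambda_s$, so likelihood,
   solves and determinants are products over an $m \times T$ grid. The
   genotype rotation is parameter-free and done once per fit; only the
   $T \times T$ generalized eigenproblem is repeated per likelihood
   evaluation.
2. **Extras** — regular genotypes with any other pattern: missing time
   points, several years, or (the common case during CV2) a single kept
   time point. They enter through the Schur complement $Q$ of the core
   block. The cross-covariance between a core record $(g, t)$ and an
   extras record $(j, t')$ is the separable product $G[g,j]\,
   \Sigma_t[t,t']$, so $Q$ and all solves stay cheap even with hundreds of
   extras records.
3. **Checks** — fixed-effect genotypes; their units are independent
   residual blocks $\Sigma_e[S_u, S_u]$.

The engine is validated in the test suite against a naive dense-$V$
implementation on balanced, CV2-like and irregular configurations; the two
agree to machine precision.

### Parameterization and optimization

Covariances are parameterized by log-Cholesky factors (off-diagonals free,
log diagonals), so every iterate is positive semi-definite by construction.
Variances are floored at $10^{-10}$ through bounds on the log-diagonals —
boundary estimates print as heritability 0.00 rather than going negative.

The REML log-likelihood (including its constant,
$-\tfrac12 (N-p)\log 2\pi$) is maximized with L-BFGS-B using analytic
gradients. The gradients use the standard identity
$\partial \ell / \partial\theta = -\tfrac12 [\mathrm{tr}(P\dot V) - y^\top
P \dot V P y]$, with every trace and quadratic form evaluated through the
same rotated/Schur representation (the test suite checks them against
central finite differences in all three record configurations). After the
first convergence the optimizer is restarted from the incumbent with a
fresh Hessian approximation until a restart no longer improves the
objective; this removes the premature flat-spot stops quasi-Newton methods
occasionally produce and is what makes the brute-force-oracle comparison
hold to $10^{-4}$ on tiny instances.

An alternative design would have been an expectation-maximization warm
start followed by average-information updates. The quasi-Newton approach
was chosen because it maximizes the identical objective under the identical
PSD parameterization with less machinery: the analytic gradient is the same
set of traces AI-REML needs, and L-BFGS-B supplies the curvature model and
the box constraints (variance floors) for free.

Starting values are moment-based: the pairwise-complete covariance of
year-adjusted genotype-level values, split evenly between $\Sigma_t$ and
$\Sigma_e$ and shrunk 20% toward its diagonal for positive definiteness.
Convergence is declared at a relative log-likelihood change below `tol`
($10^{-8}$ by default, `factr`-scaled inside L-BFGS-B) within `max_iter`
(200) iterations; non-convergence is flagged, not hidden.

### Predictions

BLUPs/GEBVs for *all* genotypes in $G$ (phenotyped or not) come from one
linear map, $\hat u = G[\cdot, obs]\, P_y\, \Sigma_t$, where $P_y$ is the
genotype-by-time aggregation of $P y$. For a genotype with no records this
reduces to the conditional expectation
$G_{new,obs} G_{obs,obs}^{-1} \hat u_{obs}$, and a genotype with zero
relationship to every phenotyped genotype is predicted at the prior mean 0
(both are asserted in the tests).

## Inference summaries

* **Heritability**: $h^2_i = \sigma^2_{g(i)} / (\sigma^2_{g(i)} +
  \sigma^2_{e(i)})$ per time point, from the fitted $\Sigma_t, \Sigma_e$
  diagonals. (The formula is indexed by a single time point; residual and
  genetic variances of the same stage.)
* **Wald test of the storage-time effect**: the contrast matrix takes
  differences of the per-time intercepts; the statistic
  $(L\hat\beta)^\top (L \widehat{var}(\hat\beta) L^\top)^{-1} L\hat\beta$
  is referred to $\chi^2_{T-1}$. This is the conditional form (all other
  fixed effects adjusted for); an incremental decomposition would be an
  alternative dialect.
* **Interaction LRT**: $2(\ell_{us} - \ell_{common})$ with degrees of
  freedom equal to the difference in covariance-parameter counts (9 for
  $T = 4$). Because the null pins correlations at 1 (a boundary), the
  nominal-$\chi^2$ reference is an approximation; the appropriate mixture
  reference for this multi-parameter boundary is not tractable in closed
  form, and the direction of the approximation error is not uniform. The
  test suite verifies the statistic is exactly 0 (p = 1) for equal
  likelihoods and well-calibrated in power simulations.
* **BIC**: $-2\ell + k \log n$ with $k$ = number of estimated covariance
  parameters and $n$ = phenotypic records after rep averaging. REML
  information criteria differ between software dialects in both $k$ and
  $n$; the convention is fixed and used consistently, which is all a model
  comparison needs.

## Crossover proportion

$\psi$ between time points $j$ and $j'$ is the proportion of genotype
pairs $(i, i')$ whose breeding-value difference changes sign strictly:
$(u_{ij} - u_{i'j})(u_{ij'} - u_{i'j'}) < 0$. Ties count as non-crossover
because the defining conditions are strict inequalities. The Monte-Carlo
version samples unordered pairs uniformly *with* replacement (100,000 by
default, seeded); the exact enumerator over all $\binom{n}{2}$ pairs makes
the replacement choice immaterial at reported precision and serves as its
oracle. $\psi$ is computed on BLUPs from the full longitudinal fit (not
per-pair refits). For bivariate-normal effects with correlation $\rho$ the
population value is $\arccos(\rho)/\pi$, which the tests verify at
$\rho \in \{-1, 0, 0.5, 0.9, 1\}$.

## Cross-validation schemes

* Folds partition the *regular* genotypes near-equally; checks are fixed
  effects, not predictable random effects, so they stay in every training
  set.
* **CV1** deletes all records of the test genotypes;
  **CV2** keeps exactly their `known_time` records in training. With the
  same master seed both schemes use identical partitions, so comparisons
  are paired by repeat.
* Prediction ability correlates GEBVs with fixed-effect-adjusted
  phenotypes (value minus the training fit's time/year estimates); a raw
  option exists. Adjusted values are the honest target because test
  genotypes sit in different years.
* PA is pooled across folds within a repeat, then averaged over repeats
  (10 folds × 10 repeats by default). Per-repeat pooling uses every test
  genotype once and avoids the small-fold instability of per-fold
  correlations; repeats with fewer than 3 usable test phenotypes at a time
  point are skipped with a warning.
* Per-repeat fold seeds derive deterministically from the master seed
  (a seeded draw of sub-seeds), so the whole pipeline is bit-reproducible.
* Each fold's optimizer warm-starts from the previous fold's converged
  covariances. Only the starting point is shared — each fold's REML
  solution is determined by its own training records and the convergence
  tolerance — and the test suite asserts record-level leakage-freedom
  through the audit trail.

## The synthetic population

The generator emulates the design of a southern highbush blueberry
advanced-selection trial: 588 genotypes, 16 checks evaluated in each of 3
years (augmented design), remaining genotypes assigned one year each,
2,000 tetraploid markers, four storage time points, 2 technical reps
averaged before analysis. Defaults, chosen once:

* Marker allele frequencies uniform on [0.05, 0.5]; dosages i.i.d.
  Binomial(4, $p_j$).
* 200 of the 2,000 markers are causal (`n_qtl`), with effect vectors
  across time points drawn from a multivariate normal scaled so the
  expected genetic variance hits the per-time heritability targets
  (default 0.5) with genetic correlations 0.9/0.7/0.4 at lags 1/2/3.
* Residual variance 1 per time point with correlations 0.25/0.1/0 by lag
  (distinct clamshell samples of one harvest unit); year effect SD 0.5;
  population mean step 0.5 per storage stage; rep noise SD 10% of the
  residual SD, present only to exercise rep averaging.

The truth object records *realized* quantities (sample variances and
correlations of the generated breeding values), not the targets.

What the generator deliberately does **not** emulate, and what that means
for reading test results:

* **No family or pedigree structure and no linkage disequilibrium**:
  genotypes are unrelated apart from marker-sampling noise. Real breeding
  populations (hundreds of families) carry far more relatedness, which is
  what REML uses to separate genetic from residual (co)variances. With an
  essentially unrelated population that separation rests only on the
  spectral spread of $G$ induced by the finite marker panel, so REML
  estimates of $h^2$ and especially of long-lag genetic correlations carry
  substantial sampling error at this scale — single-fit recovery checks at
  tight tolerances will fluctuate from seed to seed, and passing them
  should not be over-read as the expected precision on real, structured
  data (nor a miss as estimator bias: the engine's likelihood and optimum
  are verified independently).
* **Additive architecture only**, matching the additive GBLUP model; with
  `n_qtl` < panel size there is in addition a mild mismatch between the
  causal-marker relationship matrix and the all-marker $G$ used in
  fitting, as in real data.
* Scores and percentages are simulated as unbounded Gaussians; no
  missing-at-random machinery beyond the block injector for
  single-stage traits.

## Problem sizes used by the checks

The test suite validates the engine against a dense-matrix implementation
on instances of 8–12 genotypes, compares REML to brute-force maximization
on twenty random 6–10-genotype two-time instances, and runs the full
synthetic design (588 genotypes × 2,000 markers) for recovery, CV1/CV2 and
BIC behavior, with 300-genotype populations for the BIC pair. These sizes
were chosen as the smallest that demonstrate each property at study scale.

## Known limitations

* No dominance or epistatic genetic effects, and no spatial field-trial
  adjustment; the model is the additive longitudinal GBLUP.
* The interaction LRT uses the nominal-df chi-square despite the boundary
  null (see above).
* Check genotypes, being fixed, receive genomic predictions only through
  the linear map above; they do not contribute to $\Sigma_t$ estimation.
* The engine's fast path assumes records can be grouped into the three
  parts described; arbitrarily messy data still evaluate exactly but lose
  the balanced-core speedup as the share of non-modal genotypes grows.
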