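---
title: "Decision-theoretic parental selection: model, losses, and design choices"
author: "BDTSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-theoretic parental selection: model, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BDTSelect)
```

## Overview

BDTSelect ranks parental candidates in a genomic breeding program by
posterior expected loss (PEL) rather than by point-estimate breeding
values. The pipeline has three stages: (1) fit a multi-trait GBLUP mixed
model by Gibbs sampling on a genomic relationship matrix; (2) form each
candidate line's posterior-predictive multivariate normal at every
retained draw; (3) average a divergence between that predictive and the
truncated multivariate-normal distribution of selected parents over the
posterior, and select the minimum-PEL fraction. This vignette records the
model, its assumptions, the tunable parameters and the design decisions a
maintainer should know about.

## The multi-trait model

For $n$ lines and $t$ traits with one adjusted record per line,

$$ y_t = \mathbf{1}\mu_t + g_t + \epsilon_t, \qquad
   \mathrm{vec}(g) \sim \mathrm{MVN}(0, \Sigma_g \otimes G), \qquad
   \epsilon_t \sim \mathrm{MVN}(0, \sigma^2_{e_t} I), $$

with $G = WW'/p$ the genomic relationship matrix from $p$ centered,
unit-variance marker columns $W$, $\Sigma_g$ the $t \times t$ genetic
covariance among traits, and a *diagonal* residual covariance $R$ (zero
residual covariances; the common simplification that keeps the residual
update conjugate and cheap). Because each line is phenotyped once, the
random-effect design matrices are identities; multi-record and
multi-environment designs are out of scope.

Assumptions worth stating plainly: phenotypes are complete (missing cells
are rejected, not imputed — the intended input is an adjusted-means table);
genetic values are strictly additive (no dominance or epistatic
relationship matrices); traits are Gaussian on the analysis scale.

### Gibbs sampler

All full conditionals are conjugate:

* intercepts: $\mu_t \mid \cdot \sim N(\overline{y_t - g_t},
  \sigma^2_{e_t}/n)$ under a flat prior;
* genetic values: with the one-time eigendecomposition
  $G = U \Lambda U'$, the rotated rows $a_i = (U'g)_i$ are independent
  $t$-variate normals. A simultaneous diagonalization of $\Sigma_g$
  against $R$ turns all $n$ updates into elementwise operations, so a
  sweep costs two $n \times n$ by $n \times t$ products plus a $t \times
  t$ eigendecomposition rather than $n$ separate solves;
* $\Sigma_g \mid g \sim \mathrm{IW}(\nu_0 + n, S_0 + \sum_i a_i a_i' /
  \lambda_i)$;
* $\sigma^2_{e_t} \mid \cdot$ scaled-inverse-chi-square.

Eigenvalues of $G$ are floored at $10^{-8}$ (singular relationship
matrices arise whenever $p < n$), and non-finite draws abort with the
sweep index. Chains are bitwise reproducible given `seed`.

**Priors.** Defaults are weakly informative and centered on a 50/50 split
of each trait's phenotypic variance: $\Sigma_g \sim \mathrm{IW}(t + 2,
\mathrm{diag}(0.5\,\widehat{\mathrm{var}}(y)))$ (prior mean equal to its
scale) and $\sigma^2_{e_t} \sim$ scaled-inv-$\chi^2(4,
0.5\,\widehat{\mathrm{var}}(y_t))$. Both are overridable in
`mcmcControl()`; variance components can also be clamped
(`fixSigmaG`/`fixRDiag`), which is how the sampler is validated against
the exact GLS solution of the mixed-model equations
(`gblupFixedVariance()`).

**Chain schedule.** `mcmcControl()` defaults (1000 burn-in, 1000 retained,
thin 5) are sized for interactive work. Production analyses of real panels
conventionally run much longer schedules (on the order of 30,000 burn-in
sweeps and 10,000 retained draws at lag 5); nothing in the implementation
changes, only runtime.

## The parental distribution and the losses

The distribution of selected parents is the base population
$\mathrm{MVN}(\mu_1, P)$, $P = \Sigma_g + R$, truncated to the upper
orthant above the threshold vector $y_c$. Thresholds come from per-trait
rules (`traitConfig()`): an empirical quantile of the observed phenotypes
(0.1 for a trait improved downwards, 0.9 upwards, is the conventional
choice) or a fixed value on the phenotype scale. The quantile estimator is
linear interpolation of order statistics (R type 7) and is configurable,
because the threshold location shifts the whole selection; sources rarely
state which estimator produced a printed threshold, so exact reproduction
of someone else's $y_c$ may require matching their convention.

Traits improved downwards are negated — values, thresholds and the
corresponding covariance rows/columns together ($P \mapsto DPD$) — so that
internally every trait is improved upwards. `applyDirectionTransform()` is
the user-facing involution.

Per posterior draw $k$ the pipeline computes:

* the orthant probability $z = \Pr(Y > y_c)$ by Miwa's deterministic
  recursive integration (via **mvtnorm**; absolute accuracy about
  $10^{-6}$ at the default 128-point grid). Posterior draws occasionally
  produce orthant masses below that absolute accuracy; such values are
  refined by a quasi-Monte-Carlo evaluation with a relative-error
  criterion under a fixed internal seed (so results stay reproducible and
  the caller's RNG stream is untouched). $z$ is floored at $10^{-300}$
  with a warning; thresholds extreme enough to underflow $z$ should be
  relaxed instead;
* the truncated mean $\mu_S$ by the deterministic first-moment identity
  $\mu_S = \mu_1 + P q / z$, where $q_k$ is the marginal density at
  $y_{c,k}$ times the conditional orthant probability of the remaining
  traits. A seeded sampling estimator (`method = "mc"` in
  `truncatedMVNMoments()`, rejection sampling with a coordinate-Gibbs
  fallback when acceptance drops below 1%) cross-checks the identity in
  the tests. Using the analytic route means the KL loss carries *no*
  integration noise: with a degenerate (clamped) posterior the PEL equals
  the closed-form loss to machine precision, which the tests assert. At
  extreme truncation ($z < 10^{-10}$) the truncated distribution
  concentrates at the orthant vertex and $\mu_S$ is set to $y_c$ on the
  truncated traits (with the conditional mean on unconstrained ones)
  rather than dividing two vanishing quantities.

The three losses:

* **KL** — closed form per draw,
  $-\log z + \tfrac12 (\mu_S - m_o)' P^{-1} (\mu_S - m_o) - \tfrac12 S'
  P^{-1} S$ with $S = \mu_S - \mu_1$. It is a genuine KL divergence
  between the truncated parental distribution and the candidate's
  $\mathrm{MVN}(m_o, P)$, is quadratic around $\mu_S$, and at $t = 1$
  collapses to $\log(1/\Pr) + \tfrac12 i^2 h^2(h^2 - 2)$ — strictly
  decreasing in $h^2$ at fixed intensity $i$. The printed closed form
  omits the truncated distribution's covariance correction; it is
  implemented verbatim.
* **Energy Score** — the sample energy distance with Euclidean norm and
  exponent $\beta = 1$ (the standard scoring-rule default), V-statistic
  pairing so that identical samples score exactly zero.
* **MALF** — per-trait asymmetric piecewise-linear ("pinball") penalty
  around $y_c$ summed over traits, default $\tau = 0.9$: falling short of
  the threshold costs nine times more than exceeding it. $\tau$ is
  per-trait configurable.

**Candidate covariance.** The candidate predictive uses the phenotypic
covariance $P^{(k)}$ (the offspring population shares the base
population's $P$), which is the default; a $\Sigma_g$-only variant is
available (`candidateCov = "genetic"` in `lossControl()`) for users who
prefer a strictly genetic predictive.

**PEL integration.** The outer posterior integral is a strided average
over retained draws (default stride 10); the inner integral over the
candidate's phenotype is analytic for KL and Monte-Carlo for Energy/MALF
(defaults 500 candidate and 500 parental samples per evaluated draw).
None of these counts is canonical — they bound runtime, and the reported
`mc_se` (between-draw standard deviation over the square root of the
number of evaluated draws) shows when they are too small. A doubling of
the Monte-Carlo draw counts changes the Energy-Score selected set by at
most a couple of lines on the bundled fixtures, which the test suite
checks under fixed seeds.

Ranking standardizes PEL to $[0,1]$ (min 0, max 1 exactly), breaks ties
by line identifier for reproducibility, and selects
$\lfloor \text{intensity} \times n \rfloor$ lines (10% by default; 76 of
766 or 32 of 320 on the real panel sizes). Pairwise selected-set overlap
is $100 |A \cap B| / |A|$ with the common selected-set size as
denominator.

## The synthetic-data generator

`simulateMarkers()` draws biallelic dosages with per-marker allele
frequencies uniform on an interval (default 0.05–0.5), resampling
monomorphic columns. `simulatePopulation()` draws genetic values from the
matrix normal with row covariance $G$ and column covariance $\Sigma_g$,
adds independent Gaussian residuals with exactly zero residual
covariances, and records the generating truth (including the implied
per-trait heritabilities) for recovery tests.

Presets (`makeFixture()`): `tiny` (12 lines, 2 traits) for unit tests;
`dataset1_like` (200 lines, 4 traits) emulates an elite wheat trial —
trait means 80/120/103/6.3 on the days-to-heading, days-to-maturity,
plant-height and grain-yield scales, one strongly correlated trait pair
(genetic correlation 0.8), heritabilities 0.7/0.7/0.6/0.4, three traits
improved downwards with 0.1-quantile thresholds and yield upwards with a
0.9-quantile threshold; `dataset2_like` (160 lines, 4 traits) emulates a
biofortification panel with weak all-positive correlations, all
directions increasing, all thresholds at the 0.9 quantile. Phenotypic
variances are set so that the quantile thresholds sit about 1.3 standard
deviations from the mean, matching the geometry of real elite-panel
summaries.

What the generator does **not** emulate: linkage and LD structure (markers
are independent, so relatedness is weak and variance components are only
diffusely identified — see below), family/pedigree structure, selection
history, genotype-by-environment interaction, and non-Gaussian traits.
Passing tests therefore demonstrate correctness of the machinery under
the model's own assumptions, not robustness to the ways real data violate
them.

## Numerical choices and degenerate inputs

* Marker standardization uses the population (divide-by-$n$) standard
  deviation; the sample-SD convention would scale $G$ by $(n-1)/n$.
  The GRM denominator is the marker count $p$, correct for unit-variance
  columns (VanRaden's $2\sum p_j q_j$ applies to raw dosages, not
  standardized ones).
* Constant phenotype columns: the prior scale is floored so the sampler
  degrades gracefully (intercept posterior concentrates on the constant,
  GEBVs on zero) instead of failing on a zero-scale Wishart.
* Constant marker columns are an error naming the column; monomorphic
  simulation draws are resampled.
* PSD repairs add the smallest power-of-ten jitter that lets the Cholesky
  succeed and log a message; the GRM eigenvalue floor is $10^{-8}$.
* The truncated-normal Mills ratio is evaluated on the log scale, stable
  far beyond the $\alpha = 8$ range where the direct ratio underflows.
* Energy-distance cross-distance matrices are computed in blocks of at
  most ~4 million entries so large oracle comparisons stay in memory.
* `standardizePEL()` refuses constant vectors (no ordering information);
  `rankAndSelect()` refuses intensities outside (0, 1).

## Problem sizes used for validation

The test suite and `scripts/acceptance.R` validate at sizes chosen to
keep a full run in the seconds-to-minutes range: sampler-vs-GLS
equivalence at $n = 50$ with clamped variance components; genetic
covariance recovery on `dataset1_like` with a 2,000 + 1,000-draw chain;
Monte-Carlo-vs-closed-form KL agreement on 20 random bivariate
configurations at $10^5$ draws; pipeline behavior on the presets with
stride 20 and 300-draw inner sampling. With independent markers at
$n = 200$, single-trait variance components are weakly identified — the
recovery criterion is therefore coverage of the generating $\Sigma_g$
diagonals by the 95% credible intervals for at least 3 of 4 traits, which
is what near-flat likelihood directions admit; the GEBV accuracy against
simulation truth (about 0.75 on the presets) is the more stable summary.

## Known limitations

* Genomic relationship only; no pedigree $A$-matrix input.
* No fixed effects beyond trait intercepts, no marker-effect
  (SNP-BLUP/Bayes-alphabet) parameterizations, no missing-phenotype
  imputation.
* The Gibbs fallback for truncated-MVN sampling ignores autocorrelation
  when reporting the `"mc"` moment standard errors.
* Single-cycle selection only: no optimum-contribution balancing of
  genetic gain against inbreeding, and no mate-allocation optimization —
  the PEL ranking tells you *which* lines to advance, not whom to cross
  with whom.
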