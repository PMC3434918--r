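---
title: "Estimating genetic correlations between partner fitness components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic correlations between partner fitness components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

## The problem

In a legume–rhizobium mutualism, the fitness interests of the two partners
need not be aligned: a host genotype that sets many fruits is not
necessarily the one on which the bacteria form many nodules.  Whether the
two are genetically correlated — and whether that correlation changes with
the abiotic/biotic context — matters for the evolutionary stability of the
symbiosis.  `symbiocor` analyses balanced G×G×E greenhouse experiments in
which a set of *Medicago truncatula* genotypes is crossed with rhizobium
inocula ("mixes") and grown under two soil environments (here: soil spiked
with carvacrol, a thyme monoterpene that leaches into Mediterranean garrigue
soils, versus untreated control soil).  Two fitness components are counted
on every plant: fruits (host fitness) and root nodules (symbiont fitness).

The canonical design the package targets is 6 genotypes × 2 mixes
(+ an uninoculated control series) × 2 soils × 5 replicates = 180 plants,
giving `g = 12` genotype-by-mix *associations* per environment with `k = 5`
replicates each.

## The estimator

Within one environment, the associations are treated as the levels of a
single random grouping factor for the joint response
\((\text{nodule count}, \ln \text{fruit})\).  The one-way MANOVA
decomposition gives the between-association and residual cross-product
matrices

\[
H = k \sum_{i=1}^{g} (\bar y_i - \bar y)(\bar y_i - \bar y)^\top,
\qquad
E = \sum_{i=1}^{g}\sum_{j=1}^{k} (y_{ij} - \bar y_i)(y_{ij} - \bar y_i)^\top,
\]

and `H + E` equals the total corrected cross-product matrix (asserted to
`1e-10` relative in the tests).  Because the design is balanced and the
genotypes/mixes are clonal and repeatable, the expected mean cross-products
identify the broad-sense genetic and environmental covariance matrices by
the method of moments:

\[
\widehat{\mathrm{Cov}}_E = \frac{E}{g(k-1)}, \qquad
\widehat{\mathrm{Cov}}_G = \frac{1}{k}\left(\frac{H}{g-1} -
  \widehat{\mathrm{Cov}}_E\right).
\]

The broad-sense genetic and environmental correlations are the off-diagonal
of each matrix divided by the square root of the product of its diagonal,
and standard errors come from the delete-one-association jackknife

\[
\mathrm{SE} = \sqrt{\tfrac{g-1}{g}\sum_i
  (\hat\theta_{(i)} - \bar{\hat\theta}_{(\cdot)})^2},
\]

with the full pipeline (cross-products → moments → correlation) recomputed
for every leave-one-out subset.

```{r}
library(symbiocor)
dat <- simulate_experiment(sim_params(seed = 1))
estimate_correlations(dat)
```

### Numerical contracts

* **Negative genetic variances.** A method-of-moments \(\widehat{\mathrm{Cov}}_G\)
  diagonal can be negative.  It is *flagged and reported, never clamped*:
  clamping to zero would bias the jackknife SE downward.  The correlation
  is then returned as `NA` with the reason attached, and undefined
  leave-one-out replicates are dropped from the jackknife sum with the
  count adjusted and recorded (a strict mode errors instead).
* **`|r_E| ≤ 1` always**, because `E` is positive semi-definite by
  construction; `|r_G|` can exceed 1 for noisy data and is reported as-is
  with an out-of-range flag.
* **ln fruit.** The plant response is analysed as `ln(y + 1)` by default,
  because uninoculated plants on carvacrol soil plausibly set zero fruit; a
  strict `ln(y)` mode errors on zeros, naming the plant.  One policy knob
  feeds both the ANOVA and the correlation modules.
* **Major-axis fit.** The line through the bivariate genotypic means is the
  leading eigenvector of their 2×2 covariance through the centroid.  When
  both eigenvalues coincide (isotropic cloud) the axis is not identified
  and the fit errors rather than returning an arbitrary sign.
* **Balance is required**, not repaired: the moment identities above hold
  only for equal group sizes, so every consumer refuses unbalanced tables
  and names the offending cells.

### ANOVA and contrasts

`fitness_anova()` fits the fixed-effects three-way model
`y ~ M + R + ST + M:ST + M:R + R:ST + M:R:ST`.  On balanced data the
sequential and marginal sums of squares coincide (checked against a
type-II computation and an independent marginal-means oracle in the
tests).  By default the uninoculated series is excluded; a second mode
enters it as a third rhizobium level, the configuration under which a soil
main effect on fruit set becomes detectable.  Post-hoc home/away
comparisons use a pooled-variance two-sample t on plant-level values — the
conventional post-hoc under a balanced ANOVA — with Welch available behind
a flag.

## What the synthetic-data generator emulates

Real plant-level data for this design are not bundled; the generator
produces datasets with the *statistical structure the estimator assumes*,
so that every stage is testable end-to-end:

* one latent bivariate genotypic value per association and environment,
  drawn from \(N(\mu + \text{effects}, \mathrm{Cov}_G[\text{env}])\);
* i.i.d. bivariate residuals \(N(0, \mathrm{Cov}_E)\) per replicate, with
  \(\mathrm{Cov}_E\) shared across environments;
* the nodule trait rounded and truncated at zero to an integer; the
  ln-fruit trait back-transformed as `round(exp(x))`;
* uninoculated controls with zero nodules and an ln-fruit mean reduced by
  a penalty that is larger on carvacrol soil;
* a "home" effect: a latent mean-nodule bonus for the thyme-sympatric
  `NA*` genotypes with their home mix on carvacrol soil, emulating the
  genotype × soil and home/away reaction-norm patterns such experiments
  show.

### Default calibration

The defaults were fixed once, as the package's representation of a
realistic experiment of this design, and are not tuning knobs:

| quantity | default | rationale |
|---|---|---|
| means | 110 nodules, 2.6 ln-fruit | counts in the tens-to-hundreds typical at harvest |
| residual SDs | 44 nodules, 0.55 ln-fruit | per-association SEM ≈ 19–20 nodules and ≈ 0.25 ln-fruit at k = 5 |
| residual correlation | 0.075 | weak positive within-association coupling |
| genetic variances | 2600 nodules², 0.62 ln-fruit² | genotype F-ratios ≈ 6–11 against that residual, i.e. clearly detectable but far from noiseless genotypic separation |
| genetic correlation | 0.6 (carvacrol), 0 (control) | the environment-dependent alignment the package exists to estimate |
| home effect | +25 nodules | a contrast of the scale a plant-level t ≈ 2–2.5 implies |
| control fruit penalty | 0.3 / 0.8 (control / carvacrol) | uninoculated plants set fewer fruit, more so with carvacrol |

A `latent = TRUE` flag exposes the pre-rounding values, because rounding
and zero-truncation would otherwise bias the moment-convergence assertions
(within-association covariance → \(\mathrm{Cov}_E\); covariance of
association means → \(\mathrm{Cov}_G + \mathrm{Cov}_E/k\)).

The generator deliberately does **not** emulate several features of real
data: counts are latent-Gaussian-rounded rather than Poisson-like (the
estimator is a Gaussian-moment method, and at means in the tens-to-hundreds
the moment structure is what matters), strain competition within a mix and
nodule occupancy are not modelled, and the genotypic draws are independent
across environments (no cross-environment genetic correlation), so the
generator cannot be used to study G×E of *single* genotypes across soils —
only the per-environment correlation structure the estimator consumes.
Passing tests therefore demonstrate correctness of the estimator under its
own assumptions, not robustness to count-data pathologies.

## Validation at study scale, and a known limitation

The test-suite and `scripts/acceptance.R` validate the pipeline at these
problem sizes (chosen to exercise the study-scale behaviour):

* algebraic identities (moment inversion, `H + E` conservation on 1,000
  random datasets, equivalence of \(\widehat{\mathrm{Cov}}_G\) with a
  brute-force group-means path to `1e-10`);
* consistency at large `g` (1,000 associations) on latent values;
* parameter recovery over 500 simulated experiments at `g = 12`, `k = 5`:
  the mean \(\hat r_G\) is close to the generating 0.6 (the ratio-of-moments
  estimator is mildly attenuated at this `g`) and close to 0 when the
  generating correlation is 0, with the mean jackknife SE within a factor
  1.5 of the empirical SD across experiments;
* the qualitative environment contrast over 200 seeded experiments.

The limitation worth stating plainly: at `g = 12` associations with
realistically large residual noise, \(\hat r_G\) is a heavy-tailed ratio
estimator.  Its SD under a generating correlation of zero is ≈ 0.35, and
occasional experiments give `|r̂_G| > 1` or an undefined value.  As a
consequence, the probability that the carvacrol-environment estimate
exceeds the control-environment estimate in any one simulated experiment
is about 0.9 — a single experiment of this size can, roughly one time in
ten, rank the two environments the wrong way around even when the true
correlations differ by 0.6.  Jackknife SEs at this `g` are themselves
noisy and should be read as order-of-magnitude statements.  Users planning
experiments to *compare* genetic correlations across environments should
consider more genotypes per environment rather than more replicates per
association.
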