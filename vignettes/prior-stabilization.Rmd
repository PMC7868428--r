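---
title: "Stabilizing the between-group slope with slightly informative priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilizing the between-group slope with slightly informative priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcprior)
```

## The model and the problem

The multilevel latent covariate model regresses a group-level outcome on the
*latent* group mean of a predictor rather than on the unreliable observed
group mean. For person $i = 1, \dots, n$ in group $j = 1, \dots, J$,

$$
X_{ij} = X_{b,j} + X_{w,ij}, \qquad
Y_{ij} = \alpha + \beta_b X_{b,j} + \delta_j + \beta_w X_{w,ij} +
\varepsilon_{ij},
$$

with $X_{b,j} \sim N(\mu_X, \tau_X^2)$, $X_{w,ij} \sim N(0, \sigma_X^2)$,
$\delta_j \sim N(0, \tau_Y^2)$, $\varepsilon_{ij} \sim N(0, \sigma_Y^2)$,
all independent. The target parameter is the between-group slope $\beta_b$,
central to contextual-effect analyses. For balanced data its ML estimator is
the moment ratio

$$\hat\beta_b = \hat\tau_{YX} / \hat\tau_X^2 .$$

When few groups are sampled and the predictor's intraclass correlation
$\rho_X = \tau_X^2/(\tau_X^2 + \sigma_X^2)$ is small, the denominator
$\hat\tau_X^2$ is estimated with large relative error, so $\hat\beta_b$ is
highly variable. Two slightly informative conjugate priors stabilize it:

* **Direct strategy** — a normal prior on the slope,
  $\beta_b \sim N(\beta_0, \tau_Y^2/(\nu_0 \tau_X^2))$. The posterior mean
  is the weighted average $(1-w)\beta_0 + w\hat\beta_b$ with
  $w = J/(\nu_0 + J)$, so $\beta_0$ acts as a *prior guess* and $\nu_0$ as a
  *prior sample size* in pseudo-groups.
* **Indirect strategy** — a gamma prior on $1/\tau_X^2$ with shape
  $\nu_0/2$ and rate $\nu_0\tau_0^2/2$. Its posterior is
  $\mathrm{Gamma}\!\big((\nu_0+J)/2,\,(\nu_0\tau_0^2 + J\hat\tau_X^2)/2\big)$,
  and the weighted average $(1-w)\tau_0^2 + w\hat\tau_X^2$ approximates the
  posterior mean of $\tau_X^2$. Substituting it for $\hat\tau_X^2$ in the ML
  ratio bounds the denominator away from zero — a Bayesian analogue of the
  ridge technique — and attenuates extreme slopes.

Both can be applied at once: the **combined** estimator first stabilizes the
variance, then shrinks the resulting slope toward $\beta_0$. The indirect
stage comes first because the slope likelihood itself needs a usable
variance estimate; this composition order is a package design choice (the
two stages commute only in the flat limits). With $\nu_0 = 0$ every
estimator collapses to ML exactly, which the tests assert to machine
precision.

## Sufficient statistics

All estimators consume ANOVA (method-of-moments) variance components, which
are closed-form and unbiased for balanced designs: with
$MSB = n\sum_j(\bar X_j - \bar X)^2/(J-1)$ and
$MSW = \sum_{ij}(X_{ij} - \bar X_j)^2 / (J(n-1))$,
$\hat\tau_X^2 = (MSB - MSW)/n$, and analogously for the cross-products and
the outcome. Full-ML variance components would differ by $O(1/J)$, below
the resolution of the accuracy approximations. $\hat\tau_Y^2$ is the
between-group variance of the *observed* outcome (not of the level-2
residual); the distinction only rescales the direct prior's variance
parameter, and the observed-variance reading is what makes the worked
Mplus translation ($\hat\tau_Y^2 = 0.15$, $\hat\tau_X^2 = 0.1$ giving
$b = 1.5$) self-consistent. Moment estimates of variances can undershoot
zero; they are kept as-is in the statistics object, flagged by the ML
estimator, and truncated at zero inside the indirect posterior (where the
prior mass keeps the rate positive whenever $\nu_0 > 0$).

## Closed-form accuracy approximations

For each estimator the package provides first-order Taylor approximations
of bias and sampling variance, hence $MSE = \text{bias}^2 + \text{variance}$
and $RMSE = \sqrt{MSE}$. Writing $c = (1-\rho_X)/(n\rho_X)$ (the
unreliability of a group mean) and $r = \beta_w/\beta_b$:

* ML: $\ \mathrm{bias} \approx -\tfrac{2}{J-1}\{-2c + c(1+r)\}\beta_b$, and
  $\mathrm{Var} \approx \tfrac{1}{J-1}\{A\,V + (-1 - 2cr)\beta_b^2\}$ where
  $A = \rho_Y/\rho_X + c(\rho_Y/\rho_X + (1-\rho_Y)/(1-\rho_X))$ and $V$ is
  the total-variance ratio $\mathrm{Var}(Y)/\mathrm{Var}(X)$.
* Direct: bias $(1-w)\beta_0 + \{-(1-w) - \tfrac{2w}{J-1}[-2c + c(1+r)]\}\beta_b$;
  variance $w^2$ times the ML variance.
* Indirect: with $f = \tau_X^2 / ((1-w)\tau_0^2 + w\tau_X^2)$ evaluated at
  the population variance, bias
  $(f-1)\beta_b - \tfrac{2wf^2}{J-1}\{-wf(1+2c) + 1 + c(1+r)\}\beta_b$ and
  variance $\tfrac{f^2}{J-1}\{A\,V + [2wf(wf(1+2c) - 2(1+c(1+r))) + 1 + 2cr]\beta_b^2\}$.

Three numerical decisions deserve comment.

**The outcome's ICC enters through its total variance split.** $\rho_Y$ and
the ratio $V$ above use the observed outcome's between/within decomposition
(between $= \tau_Y^2 + \beta_b^2\tau_X^2$, within
$= \sigma_Y^2 + \beta_w^2\sigma_X^2$; under level-1 standardization
$V = 1$). An independent delta-method derivation of
$\mathrm{Var}(\hat\tau_{YX}/\hat\tau_X^2)$ from the exact sampling moments
of the balanced ANOVA components fixes this reading: with the total split the predicted RMSE agrees with an
independent Monte Carlo to within a few percent in a benign regime
($\rho_X = 0.4$, $n = 20$, $J = 200$), which the test suite asserts,
whereas reading $\rho_Y$ off the residual variances alone drops the
structural share $\beta_b^2\tau_X^2$ of the outcome's between-group
variance from the leading term — an understatement that does not vanish
with $J$ or $n$.

**The two flat-limit reductions are exact.** At $w = 1$ (and hence
$f = 1$) the direct formulas coincide with the ML ones term by term, and
the indirect variance's slope bracket collapses algebraically:
$2wf(wf(1+2c) - 2(1+c(1+r))) + 1 + 2cr \to 2(1+2c) - 4 - 4c(1+r) + 1 + 2cr
= -1 - 2cr$, identical to the ML bracket. There is no sign inconsistency
between the two printed forms; the tests assert the reduction to machine
precision on a 50-point parameter grid.

**$f$ is evaluated at the population variance.** The expansions are
population-level; plugging in $\hat\tau_X^2$ would mix sampling noise into
a deterministic approximation.

The expansions drop terms of order $1/n^2$ and $1/(n^2(n-1))$. They are
therefore *rough* precisely where stabilization matters most: at
$\rho_X = 0.1$ and $n = 5$, $c = 1.8$, so the dropped $O(c^2)$ terms are
comparable to the retained ones and the closed forms understate the
simulated RMSE by 40–90% (the acceptance suite measures this rather than
hiding it; see "Known limitations"). In benign regimes (larger ICC, larger
$n$) analytic and simulated RMSE agree to within a few percent, which is
what validates the implementation.

## The Monte Carlo engine

`run_study()` simulates `reps` datasets per cell of a `J` grid and applies
every configured estimator to the *same* datasets (common random numbers).
Per-replicate seeds are derived from the base seed by fixed increments, so
any single replicate can be regenerated in isolation. Aggregates per
estimator and cell: `bias = mean - beta_b`, the `(reps-1)`-divisor
variance, `mse = bias^2 + variance`, `rmse = sqrt(mse)`, and a delta-method
Monte Carlo standard error of the RMSE.

**Exclusion policy.** The ML ratio conditioned only on
$\hat\tau_X^2 > 0$ has no finite second moment — the sampling density of
$\hat\tau_X^2$ is positive at zero, so simulated RMSEs grow without bound
as replications accumulate and any comparison against ML becomes a lottery
on the single smallest denominator. The package therefore screens ML-type
replicates on *admissibility* of the between-level covariance matrix
($\hat\tau_X^2 > 0$, $\hat\tau_Y^2 > 0$, and
$\hat\tau_X^2\hat\tau_Y^2 > \hat\tau_{YX}^2$), the standard
inadmissible-solution screen in multilevel-SEM simulation work, under which
the ML RMSE is finite and stable. The policy is per-estimator and
configurable (`estimator_spec(exclude = ...)`): stabilized estimators never
exclude by default (their denominators are bounded away from zero), and
exclusion counts are reported, with cells dropping more than 5% flagged.

**Paired comparisons.** Because estimators share datasets,
`rmse_difference()` compares two estimators on their common included
replicates and reports the standard error of the *paired* squared-error
difference. For highly correlated estimators this is far sharper than
combining two marginal RMSE standard errors, and it is the margin the
ordering tests use. Note that small-$\tau_0^2$ indirect estimators are
heavy-tailed exactly on the replicates the ML screen removes, so five-way
comparisons are made on the common admissible set.

`figure1_study()` evaluates ML plus direct/indirect with correct
($\beta_0 = \beta_b$, $\tau_0^2 = \tau_X^2$) and incorrect ($\beta_0 = 0$,
$\tau_0^2 = 1$) prior guesses, analytically and by simulation;
`figure2_study()` evaluates ML plus the four combined estimators (no
analytic form exists for the combination). Default conditions: standardized
variables, $\beta_b = 0.7$, $\rho_X = 0.1$, $n = 5$, $J$ from 20 to 60,
20000 replications per cell, and $\nu_0 \in \{0.1, 1, 5\}$ as panels.

## What the simulator does and does not emulate

The generator draws exactly the model above: balanced groups, joint
normality, a single predictor, no missing data. Default conditions are
small- to medium-ICC data typical of psychology (ICC 0.1, five persons per
group, 20–60 groups). Two population parameters the comparative studies
never vary — the within-group slope and the outcome's group-level residual
variance — default to $\beta_w = 0.2$ and $\tau_Y^2 = 0.15$ (the latter
matching the worked Mplus example's $\hat\tau_Y^2$); both are exposed in
every configuration. Passing tests on these conditions show the estimators
and their accuracy theory behave as derived *under the model*; they say
nothing about robustness to non-normality, unbalanced designs, multiple
predictors, or measurement models with multiple indicators, all of which
are out of scope.

## Parameters that matter

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `beta0` | prior guess for the slope | slope scale | 0 (shrink toward null) |
| `tau0_sq` | prior guess for the group-level predictor variance | variance | 1 (standardization upper bound) |
| `nu0` | prior sample size | pseudo-groups | 1 (slightly informative) |
| `J`, `n` | groups, persons per group | counts | study grid 20–60, 5 |
| `reps` | replications per cell | count | 20000 |

A *correct* guess is not required: an over-guessed $\tau_0^2$ deliberately
attenuates the slope, trading bias for variance, and in small samples
yields the smallest analytic RMSE of the five single-prior estimators.
Pushing $\nu_0$ from 1 to 5 with that incorrect variance prior backfires —
the induced bias outgrows the variance reduction — so "slightly
informative" values in the low one-digit range are the sensible default.

## Degenerate inputs and tie-breaks

* $\hat\tau_X^2 = 0$: ML undefined (error); $< 0$: ML returns the ratio
  with a `degenerate` flag (sign contract preserved) and the indirect
  machinery truncates at zero.
* $\hat\tau_Y^2 \le 0$: the direct *posterior* (which needs a positive
  variance) errors; the direct point estimate, which only needs
  $\hat\beta_b$, does not.
* $\beta_b = 0$ with $\beta_w \ne 0$: the accuracy expansions involve
  $\beta_w/\beta_b$ and error; with both slopes zero the ratio is taken
  as 0.
* `reps = 1`: bias only, variance reported as missing.

## Known limitations

* The accuracy formulas are first-order. At the default study conditions
  they understate simulated RMSE substantially (measured factor ≈ 1.4–1.9
  at $J = 20$–60); their value there is ordinal — ranking priors and
  sample sizes — not numerical prediction. The package exposes both
  surfaces so users can see the gap.
* The exact inverse-gamma posterior mean and its weighted-average
  approximation differ by
  $2(\nu_0\tau_0^2 + J\hat\tau_X^2)/((\nu_0+J)(\nu_0+J-2))$ — about 0.015
  at $J = 20$ with $\nu_0 = \tau_0^2 = 1$ — shrinking as $1/J^2$;
  `indirect_variance_exact()` reports the exact value.
* Point estimates are closed-form posterior means (EAP). MCMC samplers
  (e.g., Mplus's Bayes module) report posterior medians; small
  median-vs-mean discrepancies are expected when comparing against actual
  Mplus runs, and no sampler is included here.
* Only balanced designs: the moment estimators and everything downstream
  assume equal group sizes.
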