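---
title: "Multistate working life expectancy: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate working life expectancy: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worklife)
```

## The question and the model

How many of the years between age 40 and age 74 can a person expect to spend
employed, jobless, or retired? `worklife` answers this with a multistate
life table. Individuals occupy one of three transient labor-force states —
*employed*, *jobless* (unemployed, inactive, students, permanently disabled,
housekeepers, and similar), *retired* — and may move back and forth between
them until they enter the absorbing state *dead* or reach the censoring age.

Movements are governed by age-specific transition probabilities
$P_a(i \to j)$, estimated from person-period transition records by
gender-stratified multinomial logistic regression. For a record with origin
state $i$ at age $a$ and covariates $x$, the probability of destination $j$
is

$$
\Pr(S_{t+1} = j \mid S_t = i, a, x) =
\frac{\exp(\eta_j)}{\sum_k \exp(\eta_k)}, \qquad
\eta_j = \alpha_j + \beta_j^\top \mathbb{1}(i) + s_j(a) + \gamma_j^\top x ,
$$

with the employed destination as the reference ($\eta_{\text{employed}} = 0$).
The linear predictor contains:

* the lagged origin state as a categorical main effect (an option interacts
  it with the age spline; off by default — the minimal parameterization
  treats the age profile as shared across origins);
* a restricted (natural) cubic spline in age, $s_j(a)$: truncated-power
  basis, linear beyond its boundary knots, $K-1$ columns for $K$ knots;
* main effects of education (low/medium/high), parity (0/1/2/3+), marital
  status (married/single/divorced/widowed) and one country-specific
  categorical covariate;
* the education $\times$ parity interaction, which lets the parity gradient
  differ by education.

Stratifying by gender implicitly interacts gender with every term.

## From probabilities to expectancies

Predicted transition matrices at a covariate profile are assembled into an
age-expanded absorbing Markov chain: composite states are (age,
labor-force state) pairs — "aged 68 and employed", "aged 69 retired" — so
the transient-to-transient matrix $U$ is block-superdiagonal (age $a$ feeds
only age $a + \text{step}$) and the final age block absorbs everyone
(censoring). The fundamental matrix

$$ N = (I - U)^{-1} $$

gives expected visits to each composite state; weighting its rows by the
radix (the state distribution at the baseline age) and multiplying by the
step length yields the expected years in each state. The three state
expectancies sum exactly to the residual life expectancy over the window —
35 years is the ceiling for the annual design (ages 40–74), 36 for the
biennial one (18 two-year occupancy points). A person in state $s$ at exact
age $a$ contributes one full step to $s$ for $[a, a+\text{step})$; no
half-interval correction is applied, which is what makes the conservation
identity and those ceilings exact.

`occupancy_forward()` implements the same quantity by forward iteration of
the occupancy vector and is used throughout the tests as an independent
oracle for the fundamental-matrix path (they agree to $10^{-10}$).

## Covariate profiles and group estimates

Population-level estimates set every categorical block to its sample
proportion (so design dummies take fractional values); group estimates set
the group's own indicator to one and the remaining blocks to within-group
proportions. The education $\times$ parity interaction cells carry the
observed joint distribution rather than the product of the margins, which
matters whenever education and parity are dependent in the records. Group
radixes default to the observed state distribution at the baseline age
within the group; a fixed vector can be supplied instead. Whether to
condition on the group's own baseline mix or the population's is genuinely
open — both are supported, the group's own mix is the default and is what
the bootstrap re-estimates per replicate.

## Mortality matching

Panel mortality follow-up can be too thin to pin down survival. When an
external period life table is supplied, the chain's mortality is adjusted
age by age: a single factor $c(a)$ scales all state-specific death
probabilities (capped at 1) so that the population death probability under
the current occupancy equals the life table's $q_x$; transient probabilities
are rescaled proportionally. The factor is found by bisection to $10^{-12}$;
the resulting survival curve reproduces the life table exactly (to
$10^{-8}$) and, because the scaling is proportional within each age, the
ordering — and very nearly the ratios — of the status expectancies is
preserved. Ages where the model says nobody dies but the life table demands
deaths have no direction to scale; this errors by default, with an optional
uniform additive shift as a fallback.

## Uncertainty

Confidence intervals are nonparametric percentile bootstrap intervals over
1,000 replications by default: persons are resampled with replacement, each
drawn person keeping their complete trajectory, so the longitudinal
dependence within persons is preserved; the whole estimation procedure —
records, fits, profiles, radixes, prediction, matching — is re-run per
replicate. The point estimate is the full-sample run, not the bootstrap
mean. Replicates that empty a stratum or an origin state are dropped and
counted (more than 5% dropped is an error). The resample index matrix is
drawn up front from the seed, so results are identical regardless of the
order in which replicates are evaluated.

Spline knots are fixed at their full-sample locations across replicates.
Re-tabulating destination counts over the precomputed design patterns is
then algebraically identical to rebuilding each resampled panel from
scratch — persons are the resampling unit and their records do not change —
which is what makes bootstrap studies cheap enough to run routinely.

## The synthetic-data generator

The generator emulates the two observation designs of register- and
survey-style panels: annual observation censored at 75, and biennial
observation censored at 76 (biennial transitions are estimated directly as
two-year steps; `thin_panel()` alternatively observes annually simulated
trajectories every second wave, which is how the slight biennial
overestimation of expectancies can be studied). Covariates are drawn
independently per person from configurable marginals — defaults are of the
order of large adult-panel samples (53% women, 60% married, parity mode at
two children, a small minority level of the extra covariate) — and are
frozen at their baseline values, since the model treats them as covariates
of the lagged-state regression rather than as dynamic states. The
initial-state mix at age 40 (employed 0.75, jobless 0.20, retired 0.05) is
an explicit configuration field: expectancies are undefined without a
baseline mix, and no convention can be inferred from data one does not
have.

The ground-truth coefficients encode what a labor economist would call
plausible annual dynamics — employment persistence around 0.93, jobless
persistence around 0.85, retirement hazard rising steeply from the late 50s,
death probabilities rising from about 0.002 at 40 to about 0.05 at 74 with
a mild education gradient — plus gender-specific parity effects and a small
education × parity interaction, so that every model term is exercised.
Because the truth lives in exactly the fitted model family,
`truth_expectancies()` provides an exact recovery target for the whole
pipeline.

What the generator does **not** emulate: time-varying covariates (parity or
marital changes after 40), calendar time and cohort structure, survey
weights, household clustering, attrition other than death, and measurement
error in self-reported states. Passing recovery tests therefore shows the
estimation machinery is correct under the stated sampling scheme, not that
real register or survey data meet these assumptions.

## Numerical choices

* Fitting: Newton–Raphson on the full stacked multinomial Hessian, records
  aggregated to unique covariate patterns (identical likelihood, much
  smaller problem). Convergence at gradient $\infty$-norm below $10^{-8}$
  per observation, at most 500 iterations, step-halving keeps the
  log-likelihood monotone. On separation (diverging coefficients or a
  singular Hessian) the fit restarts with a ridge of $10^{-6}$ and is
  flagged; a destination that never occurs then gets a predicted
  probability on the order of $10^{-8}$ rather than a crash.
* Knots: default 5 knots at the 0.05/0.275/0.5/0.725/0.95 quantiles of the
  observed origin ages — standard restricted-cubic-spline practice, exposed
  as configuration because no single placement is canonical.
* Reference categories: destination employed, origin employed, education
  low, parity 0, marital married — arbitrary but fixed.
* Structural zeros (e.g. no retired-to-employed moves in some data) are kept
  estimable by default, since back-and-forth movement is allowed in
  principle; `mask_cells()` hard-zeroes named cells and renormalizes when a
  hard constraint is wanted.
* Design columns with no variation among observed patterns are pinned at
  zero rather than left to a singular solve.
* Gapped observation pairs (a missing intermediate wave) are dropped, not
  bridged: imputing a path would inject a model the data do not state. A
  death between waves is assigned to the pair whose origin is the last
  observation alive.

## Problem sizes used in the shipped analyses

The analysis drivers and tests use synthetic panels of 20,000 persons for
the main estimates and recovery checks, 4,000 for the illustrative bootstrap
run, and a 200-dataset × 200-replicate coverage study at 2,000 persons with
a covariate-free truth; Monte-Carlo cross-checks of the expectancy algebra
use 100,000 simulated trajectories. These sizes give recovery errors of
roughly a tenth of a year on expectancies while keeping any single driver in
the minutes range.

## Known limitations

* Expectancies are discrete-time and uninterpolated; no Sullivan-style
  prevalence shortcut and no continuous-time hazards.
* Coefficient standard errors are provided for diagnostics only; interval
  estimation is the bootstrap's job.
* Matching is applied per gender-level life table to each predicted chain;
  matching within finer cells (gender × education × parity) would require
  cell-specific life tables, which period life tables rarely provide.
* Cell-level expectancies at moderate sample sizes carry sampling noise of
  a few tenths of a year (they accumulate 35 years of estimated
  probabilities, and mortality in particular rests on few observed deaths);
  the bootstrap intervals, not the point estimates, are the honest summary
  at such sizes.
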