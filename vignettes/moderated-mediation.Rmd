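---
title: "Relative deprivation, psychological capital, and health: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative deprivation, psychological capital, and health: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdhealth)
```

## The scientific problem

Rural residents compare their household income with that of their fellow
villagers. The shortfall relative to richer co-villagers — relative
deprivation (RD) — is hypothesised to harm health along three dimensions
(self-rated health, depressive symptoms, physical function), partly through
an eroded positive psychological state ("psychological capital", PC), with
absolute family income (AFI) moderating the damage. `rdhealth` implements
this analysis chain for village-clustered person-level survey tables, plus
a synthetic generator with known structural parameters so that every stage
can be validated by parameter recovery.

## Deprivation indices

Within a reference group (village) with ordered incomes
$x_1 \le \dots \le x_n$, the pairwise deprivation of person $i$ by person
$j$ is $\max(x_j - x_i, 0)$. Aggregating:

* **Yitzhaki**: $\frac{1}{n}\sum_{x_k > x_i}(x_k - x_i)$ — income units;
  equivalently $\gamma_i^{+}(\mu_i^{+} - x_i)$, where $\gamma_i^{+}$ is the
  share of the group strictly richer than $i$ and $\mu_i^{+}$ their mean
  income (a tested identity).
* **Deaton**: Yitzhaki divided by the group mean $\mu_x$ — dimensionless,
  scale-invariant, bounded in $[0, 1)$ for positive incomes.
* **Podder**: the same sum on $\ln x$ — log-income units.
* **Percentile rank**: $100\,(r-1)/(n-1)$ with average ranks at ties, so
  the unique richest scores 100 and the unique poorest 0.

Conventions where the definitions are silent: sums run over *strictly*
richer members (ties deprive no one — the pairwise primitive decides this,
even though the sorted-sum notation $k = i{+}1,\dots,n$ differs at ties);
nonpositive incomes are excluded from the Podder group with a warning
(retained for the other three, which remain defined); singleton villages
get missing indices and a logged count. A published descriptive table
reports the Podder measure with a mean near 8.4 and range up to 12.9, which
is the scale of log income itself, not of this index (bounded well below
that for any village); the formula is implemented as defined and the
discrepancy is documented rather than reconciled.

`add_rd_indices()` appends the four indices and, by default, z-scored
copies over the full sample (`*_z`), matching the convention of
standardising the main continuous variables before modelling.

## Models

**Baseline (two-level).** For outcome $y_{ic}$ of person $i$ in village
$c$: $y_{ic} = \beta_0 + \beta_1 RD_{ic} + \beta_2 X_{ic} + \zeta_c +
\varepsilon_{ic}$ with a village random intercept $\zeta_c$. Self-rated
health is dichotomised (default: 4–5 "good" vs 1–3 "bad"; the cut-point is
a configurable choice because the 1–5 scale itself does not fix it, and the
published models never state it) and fitted as a mixed logistic regression
reported with odds ratios ($e^{\beta}$); the depression (CES-D, 8–32) and
physical-function (PADL, 0–7, measured only above age 45) scores use linear
mixed models. Estimation is maximum likelihood via `lme4` (adaptive
Gauss–Hermite quadrature, 5 points, for the logistic fit; ML, not REML, for
the linear fits), deterministic given the data. Fit statistics: McFadden
pseudo-$R^2$ (logistic, against the random-intercept null) or marginal
$R^2$ (linear), log-likelihood, cluster counts, and complete-case
accounting (listwise deletion; dropped rows are counted).

**Mediation.** The product-of-coefficients scheme fits (i) outcome on RD
and controls (total effect $\alpha_1$), (ii) PC on RD and controls (a-path
$\beta_1$), (iii) outcome on RD, PC and controls (direct $\chi_1$, b-path
$\chi_2$); the indirect effect is $\beta_1\chi_2$. These regressions are
single-level, exactly as the equations are written; because the data are
village-clustered, standard errors default to village-cluster-robust
(sandwich), with an iid option. For the linear outcomes
$\alpha_1 = \chi_1 + \beta_1\chi_2$ holds exactly on complete data and is
asserted in tests; on the log-odds scale the identity fails by
non-collapsibility and is only documented. Percentile-bootstrap confidence
intervals resample individuals by default (whole villages optionally),
B = 1000 by default, with the seed recorded in the result; failing
replicates are redrawn up to a logged cap. Effect proportions are
magnitude-based, $|indirect|/(|direct|+|indirect|)$ — the formula that
reproduces published effect-proportion columns from their printed effect
values. (One published physical-function row pairs the larger magnitude
with the smaller proportion, an apparent label swap; this package always
reports proportions consistent with its own estimates.)

**Moderation.** Four nested regressions per dependent variable: controls;
+RD; +AFI (log per-capita household income); +the product of mean-centered
RD and mean-centered AFI. Both interacting variables are centered (the
symmetric convention — centering only one changes nothing substantive),
making the interaction slope invariant to location shifts. Step
$R^2$ is non-decreasing in the linear case. Simple slopes at AFI ±1 SD are
reported as an optional extension, as is a Holm-adjusted significance
column across tested dependents; the headline convention remains two-sided
5% without multiplicity correction.

**Direct-path versus total-effect moderation.** In a moderated-mediation
design, moderation of the a-path necessarily transmits to the *total*
effect of every outcome the mediator feeds (here, a mediator interaction of
0.235 and a PC-to-CES-D slope of −1 make the total-effect CES-D interaction
clearly nonzero). What distinguishes the outcomes is whether their *direct*
paths are moderated. `moderate_hierarchical(include_mediator = TRUE)`
conditions every step on PC so the step-4 interaction probes the direct
path; the pipeline's moderated-mediation summary uses this for outcomes and
the plain four-step equations (the default) for the mediator.

## The synthetic generator

`sim_config()` / `generate_population()` emulate a CFPS-like rural
household survey: village mean log incomes (default between-village SD
0.4), lognormal resident incomes (within SD 0.8; mean log income 9.28, so
mean income ≈ 16,000 yuan), control covariates with marginals matched to
published descriptives (mean age 46, half male, 80% married, 82% employed,
92% insured, household size ≈ 4.5), standardized within-village Deaton
deprivation computed by the same code used for analysis, and:

* a latent mediator $PC^* = 3.6 - 0.2\,zRD + 0.1\,zAFI +
  0.235\,(zRD\!-\!\overline{zRD})(zAFI\!-\!\overline{zAFI}) + controls +
  \zeta_c + N(0, 0.55)$, observed on 1–5;
* self-rated health from an ordered-logit latent with fixed cutpoints, so
  its good/bad dichotomisation is *exactly* a random-intercept logistic
  model whose RD coefficient (direct −0.56 plus mediated −0.2×0.336 ≈
  −0.63 total) yields the calibrated odds ratio ≈ 0.53;
* CES-D and PADL as rounded-and-clipped linear latents (intercepts 14.5 and
  6.6; direct RD effects +1.4 and −0.4; mediator effects −1.0 and +0.092;
  interaction effects +0.3 on health status, 0 on CES-D, −0.3 on PADL).

Village sizes are uniform on 20–40 by default (surveys rarely publish
them); PADL is missing exactly for age ≤ 45, mirroring the instrument;
controls are generated independently of income unless
`confounded_controls = TRUE` (education then loads on income, for
robustness testing).

**Measurement design.** Bounded ordinal scales attenuate regression slopes
if the latent construction ignores them: the deprivation-by-income product
regressor is one-sided and heavy-tailed (within villages the Deaton score
is almost a deterministic decreasing function of income, so the centered
product behaves like $-zRD^2$), and its high-leverage observations are
precisely the ones a careless latent scale pushes past the scale
boundaries. Three choices keep the observed-scale coefficients equal to the
generating ones to within ~2%: (1) *dithered rounding* — uniform
$U(-\tfrac12,\tfrac12)$ measurement noise added before fixed half-integer
thresholds — which makes the discretised conditional mean exactly linear
away from the boundaries; (2) a mid-scale mediator intercept (3.6) with
modest residual noise (0.55), leaving the one-sided interaction downward
headroom (boundary contact < 1%); (3) a CES-D floor share near 3%
(intercept 14.5, noise 2.7). These are generator design choices, measured
by paired latent-versus-observed fits during development. The price is a
mediator centred near 3.4 rather than the published 4.15 and a CES-D mean
of 14.5 versus 13.8; the ceiling-skew of real instruments is exactly the
feature the generator trades away for an unbiased recovery surface, and
passing recovery tests therefore do **not** certify behaviour under heavy
ceiling effects.

**What a "generated null" means.** The fitted a-path equation conditions
only on RD and the controls. Because RD and AFI are strongly negatively
correlated within villages, any AFI or interaction path into the mediator
leaks into that fitted coefficient. Null-scenario tests therefore zero
*all* mediator inputs, and path-recovery scenarios for the plain mediation
equations zero the AFI and interaction paths; the full calibrated scenario
recovers $\beta_1$ and the interaction jointly from the step-4 moderation
fit, which is the correctly specified equation for the mediator.

## Numerical choices and degenerate inputs

Index computation is $O(n\log n)$ per village via suffix sums over
distinct incomes, verified to 1e-12 against the $O(n^2)$ pairwise loop.
Optimizers: `bobyqa` for the mixed logistic fit; convergence failures
raise errors carrying the optimizer messages rather than returning silent
garbage. Degenerate designs — single village, one outcome class, constant
mediator, constant interaction column, collinear controls — raise named
errors. Bootstrap replicates that fail are redrawn with a capped, logged
retry count. All randomness is seeded: identical configs give
byte-identical populations, identical bootstrap seeds give identical
intervals.

## Problem sizes

Default study conditions are 100 villages × 20–40 residents (~3,000
people). Recovery checks use 200 replicates of 100 × 30; the bootstrap
null check uses 200 replicates of 40 × 25 with B = 500; decorrelation
checks use ~20,000 people. These sizes give Monte-Carlo standard errors
comfortably below the tolerances being asserted (e.g. ≈0.5% of the
interaction effect) while a full test run stays in a few minutes.

## Known limitations

* Associational models only: no causal mediation estimands, no KHB-style
  rescaling for the logistic path, single mediator.
* Village-level reference groups only; no survey weights, panel structure,
  or imputation — complete-case analysis throughout, with counts reported.
* The generator does not emulate ceiling-skewed mediator/outcome
  distributions, informative village sizes, or control–deprivation
  confounding (beyond the single `confounded_controls` switch).
* Published coefficient tables this package is calibrated against print
  AFI terms on inconsistent scales across models; the package uses one
  documented scaling (z-scored log income) and does not chase those cells.
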