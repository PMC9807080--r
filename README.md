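# rdhealth

Relative income deprivation and health inequality in village-clustered
survey data: deprivation indices, two-level health-outcome models,
bootstrap mediation through psychological capital, and moderation by
absolute family income — with a synthetic survey generator that makes every
stage testable by parameter recovery.

## Who this is for

Researchers analysing person-level rural household surveys (incomes, 1–5
self-rated health, CES-D depression totals, activities-of-daily-living
scores) who want the standard relative-deprivation analysis chain as
tested, reproducible code rather than ad-hoc scripts: compute each
resident's deprivation relative to their village, fit the baseline
mixed models, decompose effects through a psychological mediator, and test
whether absolute income softens the deprivation effect.

## The statistics at the core

Within a village with incomes $x_1 \le \dots \le x_n$, person $i$'s
deprivation is measured four ways:

$$\text{Yitzhaki}_i = \frac{1}{n}\sum_{x_k > x_i}(x_k - x_i)
  = \gamma_i^{+}\,(\mu_i^{+} - x_i), \qquad
  \text{Deaton}_i = \frac{\text{Yitzhaki}_i}{\mu_x} \in [0, 1),$$

$$\text{Podder}_i = \frac{1}{n}\sum_{x_k > x_i}(\ln x_k - \ln x_i), \qquad
  \text{Percentile}_i = 100\,\frac{r_i - 1}{n - 1},$$

with $\gamma_i^{+}$ the share of the village strictly richer than $i$ and
$\mu_i^{+}$ their mean income. These feed three model layers:

1. **Baseline**: $y_{ic} = \beta_0 + \beta_1 RD_{ic} + \beta_2 X_{ic} +
   \zeta_c + \varepsilon_{ic}$ with village random intercepts — mixed
   logistic for dichotomised self-rated health (odds ratios), linear mixed
   models for CES-D and PADL (`lme4`).
2. **Mediation**: the product-of-coefficients indirect effect
   $\beta_1\chi_2$ (RD→PC times PC→outcome) with percentile-bootstrap
   confidence intervals and magnitude-based effect proportions.
3. **Moderation**: four-step hierarchical regressions adding controls, RD,
   log family income (AFI), and the centered RD×AFI product.

## Worked example

```r
library(rdhealth)

pop <- add_rd_indices(generate_population(sim_config(seed = 1)))
dplyr::select(pop, village_id, income, rd_deaton, rd_percentile)[1:4, ]
#> # A tibble: 4 × 4
#>   village_id income rd_deaton rd_percentile
#>        <int>  <dbl>     <dbl>         <dbl>
#> 1          1 26892.     0.255          77.3
#> 2          1  4922.     0.782          0
#> 3          1 14121.     0.459          36.4
#> 4          1 10519.     0.565          27.3
```

Resident 2 earns 4,922 yuan, the least in the village (percentile 0); the
mean shortfall relative to richer co-villagers is 78% of the village mean
income (Deaton 0.78).

```r
fit_baseline(pop, "srh_binary", rd = "deaton")
#> <rd_fit> logistic srh_binary model, RD = rd_deaton_z
#>         term    OR    se
#>  (Intercept) 0.658 0.303
#>  rd_deaton_z 0.571 0.043
#>  ...
#> N = 2992 (100 villages, 0 rows dropped); log-likelihood = -1828.0; McFadden R2 = 0.055
#> Random-intercept variance = 0.1313
```

One standard deviation more deprivation multiplies the odds of reporting
good health by 0.57.

```r
mediate_bootstrap(pop, "cesd", rd = "deaton", n_boot = 1000, seed = 1)
#> <rd_mediation> outcome = cesd (linear), RD = deaton, N = 2992
#>   total  =    1.670
#>   direct =    1.365  95% CI [1.261, 1.467]  (percentile-bootstrap)
#>   indirect =  0.306  95% CI [0.256, 0.355]  (a = -0.308, b = -0.993)
#>   effect proportions: direct 81.7%, indirect 18.3%
#>   bootstrap: B = 1000, unit = individual, seed = 1, both significant: TRUE
```

Deprivation raises the depression score by 1.67 points per SD in total;
0.31 of that travels through eroded psychological capital (a negative
a-path times a negative PC→CES-D path), and neither bootstrap interval
contains zero.

```r
moderate_hierarchical(pop, "pc", rd = "deaton")
#> <rd_moderation> dependent = pc (linear), RD = deaton, N = 2992
#>   RD x AFI = 0.233  95% CI [0.212, 0.255]  p = 8.73e-102 *
#>   main RD = -0.183, main AFI = 0.121
#>   step R2: 0.0200 -> 0.1560 -> 0.1618 -> 0.2552
#>   RD slope at AFI -1 SD: -0.417, +1 SD: 0.050
```

The positive interaction means higher absolute income attenuates the
negative deprivation effect on psychological capital: the deprivation
slope is −0.42 one SD below mean income and essentially flat one SD above.

`run_pipeline()` chains all stages (3×3 baseline grid, mediation and
moderation per outcome, a moderated-mediation summary table, and a
reproducibility manifest); `tidy()`, `glance()` and `autoplot()` methods
cover every fitted object. `write_population()` / `read_population()`
round-trip the person-record CSV schema.

## Vignette

`vignettes/moderated-mediation.Rmd` documents the model equations and
their assumptions, every generator parameter with its default and
rationale, the measurement design that makes generating coefficients
recoverable on the observed ordinal scales, what a "generated null" means
in a correlated-regressor design, and the package's limitations.
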