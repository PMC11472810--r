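# twinliab

Classical twin-design analysis of binary (dichotomous) phenotypes in R:
liability-threshold ACE modelling, maximum-likelihood tetrachoric
correlations, questionnaire-based phenotype coding with exclusion rules,
descriptive epidemiology, and a cohort simulator for method validation.

The package was built around the analysis of parent-reported speech and
language difficulties (SaLD) in a large population-based twin registry, where
individual-level data are restricted: every stage of that analysis is
reproducible here on simulated cohorts with the same statistical structure
(five zygosity-by-sex groups, sex-specific prevalence, configurable variance
components).

## The model

A binary trait is assumed to arise from a latent standard-normal *liability*:
a twin is affected when liability exceeds the threshold
τ = Φ⁻¹(1 − prevalence). Liability variance is decomposed into additive
genetic (A), shared environment (C), and non-shared environment plus
measurement error (E), with a² + c² + e² = 1. Twin-pair liabilities are
bivariate normal with correlation

- r(MZ) = a² + c² (monozygotic pairs share all of A and C),
- r(DZ) = ½·a² + c² (dizygotic pairs, same- or opposite-sex, share half of A).

Concordance tables per zygosity group are fitted by maximising the joint
multinomial likelihood with cell probabilities from the bivariate-normal
orthant P(X > τ₁, Y > τ₂; r), computed via Plackett's identity to better than
1e-10. Model comparison uses −2 log-likelihood differences against the
saturated model (χ² with Δdf = difference in free parameters); confidence
intervals are profile likelihood.

## Worked example

```r
library(twinliab)

# five-group cohort with registry-scale defaults:
# 2465/2676/3122/2739/5772 pairs, a2 = 0.75, c2 = 0.22, e2 = 0.03,
# prevalence 10.61% (male) / 5.03% (female)
cfg    <- sim_config(seed = 4)
cohort <- simulate_cohort(cfg)
coded  <- code_sald(cohort, model = 1)
aset   <- pair_analysis_set(coded)
tabs   <- group_tables(aset$pairs)

summarise_prevalence(aset)$prevalence
#> # A tibble: 3 × 7
#>   group   affected total proportion ci_low ci_high method
#>   <chr>      <int> <int>      <dbl>  <dbl>   <dbl> <chr>
#> 1 overall     2605 33548     0.0776 0.0748  0.0805 wald
#> 2 male        1800 16946     0.106  0.102   0.111  wald
#> 3 female       805 16602     0.0485 0.0452  0.0518 wald

tetrachoric_by_class(tabs)
#> # A tibble: 2 × 6
#>   class   rho ci_low ci_high n_pairs boundary
#>   <chr> <dbl>  <dbl>   <dbl>   <dbl> <lgl>
#> 1 DZ    0.596  0.558   0.632   11633 FALSE
#> 2 MZ    0.970  0.960   0.979    5141 FALSE

fit <- fit_variance_model(tabs, "ACE", ci = "profile")
fit$components
#> # A tibble: 3 × 5
#>   component estimate ci_low ci_high free
#>   <chr>        <dbl>  <dbl>   <dbl> <lgl>
#> 1 a2          0.741  0.666   0.820  TRUE
#> 2 c2          0.230  0.152   0.303  TRUE
#> 3 e2          0.0289 0.0206  0.0396 TRUE
```

Interpretation: about 74% of the variance in liability is attributable to
additive genetic factors, 23% to shared environment, and ~3% to non-shared
environment and measurement error — the simulated truth (0.75 / 0.22 / 0.03)
lies inside every profile interval, and the MZ tetrachoric correlation 0.970
matches the implied a² + c² = 0.97.

`run_pipeline()` chains all of the above (plus AE/CE/E fits and the
likelihood-ratio ladder) into one report bundle, `autoplot()` renders the
stacked A/C/E variance figure, and `inst/scripts/run_pipeline.R` wraps it
for shell use.

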