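# ssdclines

Do male and female arthropods change body size to the same degree along
latitude, altitude and the seasonal temperature cycle? `ssdclines`
implements a complete synthesis pipeline for that question, aimed at
ecologists compiling sex-separated field body-size clines across many
studies and species.

## What it computes

For every study × species × sex the package fits the exponential size cline

    ln(dry mass, mg) = alpha + beta * x,    x = latitude (°) | altitude (m) | seasonal temperature (°C)

by OLS, and re-expresses the slope as a percent change in mass per
reporting unit, `(exp(beta * u) - 1) * 100` (u = 1 for latitude and
temperature, u = 150 m of elevation ≈ 1 °C). Heterogeneous size metrics
(lengths, volumes, wet masses) are first converted to dry mass through a
registry of published regressions.

The sexes are then compared within each study by two signed, symmetric
statistics:

* **size-cline ratio** = (larger cline / smaller cline) − 1, positive when
  the male percent-change is greater in magnitude — the response variable
  of the synthesis;
* **SDI** (Lovich–Gibbons) = (mass of larger sex / mass of smaller sex) − 1,
  positive when males are larger, evaluated at each study's gradient
  midpoint.

Ratios are synthesised with an inverse-variance-weighted linear mixed model
(weights = 1 / summed slope variances; nested class/order/family/species
random intercepts, via lme4). The pipeline reports the overall weighted-mean
ratio with a t test against zero, all-subsets AICc model selection over the
moderators (environment type, voltinism, mean species mass, cline
direction, SDI) with "full" model averaging, a weighted F test between
taxonomic orders, a single-pass 1.5 × IQR outlier re-run, sign-concordance
classification of discordant pairs, and a reduced-major-axis (RMA)
allometric cross-check with continuity-corrected chi-square counts and
coefficient-of-variation contrasts.

A synthetic-data generator with exact ground truth
(`generator_config()` / `generate_dataset()` / `recovery_experiment()`)
supports bias, coverage and model-selection recovery experiments.

## Worked example

```r
library(ssdclines)

cfg <- generator_config(gradient_type = "latitude", n_studies = 60, seed = 42)
ds  <- generate_dataset(cfg)          # known truth: overall ratio = 0
run <- run_full_analysis(ds$observations)
print(run)
#> latitude: 60 pairs; male stronger in 60% of cases; weighted mean 0.03
#>   (+/- 0.26 95% CI), t(55) = 0.19, p = 0.85

head(run$latitude$model_selection$table, 3)
#>               terms k log_likelihood     aicc delta_aicc akaike_weight
#> 1            (null) 6      -68.45991 150.5047  0.0000000     0.2580124
#> 2               sdi 7      -67.49576 151.1454  0.6406322     0.1872962
#> 3 mean_species_mass 7      -68.11815 152.3901  1.8854095     0.1005146

run$latitude$averaged_coefficients
#>                     term   estimate         se         z         p
#> 1            (Intercept) 0.05572567 0.20976265 0.2656606 0.7905006
#> 2                    sdi 0.14833732 0.23022799 0.6443062 0.5193769
#> 3                ln_mass 0.01288272 0.02980458 0.4322397 0.6655672
#> 4 environmentterrestrial 0.02548746 0.07976196 0.3195441 0.7493140
#> 5  voltinismmultivoltine 0.01506941 0.06730511 0.2238969 0.8228375
```

Reading the output: neither sex responds consistently more than the other in
this dataset — the weighted-mean ratio (0.03) is indistinguishable from
zero, the null model wins the AICc ranking, and no model-averaged moderator
approaches significance; all as expected, since the data were generated
with a true overall ratio of 0 and no moderator effects. The same run also
reports the outlier re-run (here 2 pairs removed, post-outlier mean 0.02 ±
0.24), the between-orders F test, concordance counts and the RMA/CV
plasticity table (`run_summary(run)` condenses everything to plain lists).

Real compilations enter through a CSV in the documented schema
(`read_observations()`, with `validate_dataset()` enforcing pairing and
minimum cline length, and a conversion registry for non-dry-mass metrics);
see the methods vignette (`vignettes/methods.Rmd`) for the model,
assumptions and design decisions.

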