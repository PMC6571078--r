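---
title: "Methods: synthesising male and female body-size clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesising male and female body-size clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdclines)
```

## The question and the estimand

Within an arthropod species, adult body size commonly changes along latitude,
altitude and the seasonal temperature cycle. `ssdclines` asks whether males
and females respond to the same gradient to the same *proportional* degree,
i.e. whether sexual size dimorphism (SSD) itself varies along major
environmental gradients.

For each study, species and sex the package fits the exponential cline

$$\ln(\text{dry mass, mg}) = \alpha + \beta \, x + \varepsilon,$$

where $x$ is latitude (°), altitude (m a.s.l.) or seasonal temperature (°C).
The slope is re-expressed as a percent change per reporting unit,
$(e^{\beta u} - 1)\times 100$, with $u = 1$ for latitude and temperature and
$u = 150$ for altitude (a 150 m rise approximates 1 °C of cooling). Working
on the log scale makes the comparison between the sexes proportional: if
both sexes change by the same percentage, a strongly dimorphic species shows
no signal, whereas absolute (linear) slopes would differ purely through the
size difference.

Two bespoke statistics compare the sexes within a study:

* **Size-cline ratio** = (larger cline / smaller cline) − 1, computed on the
  percent-change scale and signed positive when the male response is the
  larger in magnitude. It is symmetric around zero and does not require the
  sexes to have been measured at exactly matched stations.
* **SDI** (Lovich–Gibbons) = (mass of larger sex / mass of smaller sex) − 1,
  signed positive when males are larger, computed from both sexes' predicted
  masses at the study's gradient midpoint.

The size-cline ratio is the response variable of the synthesis; SDI, mean
species mass, environment type, voltinism and the direction of the cline are
candidate moderators.

## Weighted hierarchical synthesis

Ratios from different studies differ hugely in precision, and species are
phylogenetically dependent. Both are handled by an inverse-variance-weighted
linear mixed model with nested taxonomic random intercepts
(class / order / family / species), fitted with `lme4`:

* **Weights.** Each pair's weight is the inverse of the *sum* of the two
  sexes' OLS slope variances — the variance of the slope difference, which
  down-weights a pair when either sex's cline is noisy. The combiner is a
  documented choice (a mean-of-variances switch is provided); only the sum
  has the slope-difference interpretation. Weights enter with the standard
  mixed-model semantics: the residual variance of observation $i$ is
  $\sigma^2 / w_i$, with $\sigma^2$ estimated.
* **Overall mean.** The headline quantity is the intercept of the null
  (intercept-only) model, fitted by REML: an overall weighted-mean ratio.
  It is tested against zero with a t statistic on
  $df = n - (\#\text{fixed effects}) - (\#\text{variance components})$.
  Denominator-df conventions for mixed models differ between tools and none
  is canonical; this rule is reported transparently with every result.
* **Moderators.** All $2^k$ subsets of the global fixed-term set (null model
  included) are fitted and ranked by AICc, with
  $k$ counting fixed effects, variance components and the residual.
  Candidate models are fitted with **maximum likelihood**, not REML:
  restricted likelihoods are not comparable across fixed-effect structures,
  so ranking REML fits by AICc would be meaningless. The null-model
  intercept reported as the overall mean still comes from the REML fit.
  Voltinism is dropped from seasonal-temperature candidate sets, where every
  species is multivoltine by definition of the gradient.
* **Model averaging.** Coefficients are "full" model-averaged: averaged over
  the entire candidate set with the coefficient (and its variance) set to
  zero in models that omit the term. This deliberately shrinks weakly
  supported effects towards zero. The unconditional standard error is
  $\sum_m w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2}$ and significance is a
  two-sided normal z test.

### Numerical choices

Profiled REML/ML surfaces are nearly flat in the variance of grouping
factors with very few levels (two taxonomic classes is the norm here), and a
single optimizer run can stall on a spurious local optimum with an absurdly
large class-level variance. Every mixed-model fit is therefore run with two
optimizers (BOBYQA with a 50 000-evaluation budget, then lme4's default
NLopt wrapper) and the fit with the better criterion value is kept.
Boundary (zero) variance components are expected — most species contribute
one or two ratios — and are retained as legitimate estimates, not errors.
AICc ties are broken by fewer parameters, then lexical term order, so
rankings are deterministic.

## Outliers, concordance, and the allometric cross-check

Because the smaller cline is the denominator of the ratio, a near-zero
denominator produces arbitrarily large ratios, and an exactly-zero one is
undefined (flagged as a sentinel and excluded from modelling). A single-pass
interquartile fence (quartiles by linear interpolation, type 7; fences at
$Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$) is applied once —
fences are *not* recomputed after removal — and the synthesis is re-run on
the retained pairs. The quartile convention matters: outlier counts change
under other quantile definitions, so it is fixed and documented.

Pairs whose slopes disagree in sign are kept but classified
(`discordant_both_ns` / `one_ns` / `both_sig` by how many of the two 95%
slope CIs exclude zero), since apparent sign discordance is usually
indistinguishable from noise.

The allometric module provides the classical alternative view: within each
study, log10 male mass is regressed on log10 female mass by reduced major
axis (slope = sign(r) × sd ratio), a slope below 1 meaning females are the
more responsive sex. Studies are matched per station, which typically loses
a large fraction of the data — the reason the size-cline ratio is the
primary statistic. Counts of female- vs male-more-responsive studies are
tested against equality with a chi-square that applies the Yates continuity
correction by default (a switch disables it for comparison with sources
that report the uncorrected statistic), and per-sex coefficients of
variation among stations (sample sd / mean × 100) are contrasted with a
paired t test on per-study differences — pairing within study is the only
design the data structure supports.

## Mass standardisation

Published clines report lengths, volumes, wet and dry masses. All sizes are
converted to dry mass (mg) through a registry of published regressions
(power law $aL^b$, its log-log-linear re-parameterisation, dry-weight
fraction, or identity), referenced per record by `conversion_id`. Units are
mg, mm and mm³ unless a registry entry's source note says otherwise.
Conversion-regression uncertainty is *not* propagated into the weights;
only the cline-fit variances are. Note that a power-law conversion of a
log-linearly varying length multiplies the fitted ln-mass slope by exactly
$b$ — conversions change the scale, not the shape, of a cline.

## What the synthetic generator emulates

The generator (`generator_config()`, `generate_dataset()`) produces datasets
with the statistical structure the synthesis assumes, plus the ground truth
needed for recovery experiments:

* 60 studies of 8 stations each by default, each study sampling an evenly
  spaced window covering 50–100% of the gradient extent (latitude 20–60°,
  altitude 0–2000 m, season 5–25 °C);
* female slopes Normal(−0.025, 0.004) per degree latitude (scaled
  equivalently for the other gradients): single-direction, decline-dominated
  clines of a few percent per unit, the typical magnitude for arthropod
  field clines;
* a true ratio per study, `mu + covariate effects + species effect
  (sd 0.5) + study effect (sd 0.25)`; the male cline is *derived* from the
  female cline and this target on the percent-change scale, so the estimand
  is exact by construction;
* female-biased SSD (SDI Normal(−0.4, 0.3)), species midpoint masses
  lognormal around 5 mg (sdlog 1.5, roughly 0.05–500 mg);
* multiplicative lognormal measurement noise with a per-study sd drawn
  uniformly from 0.05–0.15 on the ln-mass scale, so slope variances — and
  hence the weights — genuinely differ between studies;
* balanced nested taxonomy (2 classes / 6 orders / 15 families / 30
  species) with studies assigned to species cyclically, so species
  typically contribute two ratios, mirroring compilations in which a few
  dozen species underlie substantially more clines.

Because all default female slopes share one sign, the gradient-direction
covariate is constant in generated data; candidate models containing an
inestimable term are dropped with a warning. This is deliberate: it mirrors
strongly direction-biased compilations and exercises the degenerate-term
path.

What the generator does **not** emulate: real phylogenetic covariance
(taxonomic nesting is a proxy, exactly as in the analysis model),
unbalanced station designs and missing stations within a sex, correlated
male–female residuals within a station, conversion-regression error, and
publication bias. Passing recovery tests therefore show that the machinery
is unbiased and calibrated *under its own assumptions* — not that those
assumptions hold for any particular field compilation.

## Recovery experiments and their observed behaviour

`recovery_experiment()` repeats generate → standardize → fit → pair →
synthesize over independently seeded replicates and summarises bias, RMSE
and CI coverage of the weighted-mean ratio, optionally adding the AICc
ranking and model-averaged moderator tests per replicate. The shipped tests
use 60-study datasets with a true overall ratio of 0: bias over 200
replicates, coverage over 500, and the null-model AICc ranking over 150 —
sizes at which the Monte-Carlo error of each summary is small relative to
its tolerance.

Two behaviours of the procedure itself (not bugs, and worth knowing) show
up in these experiments. First, the ratio estimator carries a small negative
Jensen-type bias (≈ −0.05 under default conditions): when the true ratio is
negative the noisier, smaller male cline sits in the denominator, and the
convexity of $1/x$ inflates negative ratios slightly more than positive
ones. Second, interval coverage sits near the top of its nominal band
(≈ 0.97): occasional heavy-tailed replicates inflate the estimated residual
scale, and spurious small positive variance components at the class/order
levels (2 and 6 levels only) widen intervals conservatively.

## Known limitations

* The weight (inverse summed slope variance) captures cline-fit precision
  but not the denominator's proximity to zero, so a pair with a tiny but
  precisely estimated smaller cline can carry a large ratio at full weight —
  the motivation for the outlier re-run.
* With one ratio per species for most species, the species-level variance
  is weakly identified from the residual; boundary estimates are routine.
* The F test between orders treats pairs as independent given weights; it
  ignores the within-order species clustering and is anti-conservative when
  species effects are strong.
* Percent-of-cases summaries are computed over finite (non-sentinel) ratios
  before outlier removal.
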