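---
title: "Methods: premature NCD mortality, risk-factor scenarios and life-table gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: premature NCD mortality, risk-factor scenarios and life-table gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdproj)
```

## The problem

SDG target 3.4 asks countries to cut premature mortality from
non-communicable diseases (NCDs) by one third by 2030. The indicator is the
*unconditional probability of dying between exact ages 30 and 70*
(written $_{40}q_{30}$, here "UPoD"): the chance that a 30-year-old dies
before 70 from the tracked causes — cancers, cardiovascular diseases,
asthma and COPD, and diabetes mellitus — absent competition from other
causes. Whether a country (and each of its provinces, by sex) will reach
the target depends on mortality trends and on six modifiable risk factors:
diabetes, raised blood pressure, high body-mass index, physical
inactivity, smoking and salt intake. `ncdproj` implements the whole
comparative-risk pipeline: indicator computation, projection to 2030,
attributable and avoidable deaths under counterfactual exposure scenarios,
achievement classification, and life-expectancy gains from cause deletion.

Because national death-registry and risk-factor survey microdata are
restricted, the package includes a synthetic-data module that emulates
those sources with known ground truth. Every downstream stage is exercised
and tested against that stated world.

## The indicator

Age-band death rates are ratios of pooled deaths to pooled person-years
($_5m_x$ = deaths/population; national rates pool numerators and
denominators, never average ratios). Rates convert to conditional death
probabilities with the mid-interval convention $a_x = n/2$:

$$_5q_x = \frac{5\,{}_5m_x}{1 + 2.5\,{}_5m_x},$$

capped at 1 for extreme rates, and the indicator multiplies survival
across the eight bands $[30,35)\dots[65,70)$:

$$_{40}q_{30} = 1 - \prod_x (1 - {}_5q_x).$$

Cause-specific values use cause-specific rates in the same formula (the
cause is treated as acting alone; no competing-risk adjustment). This is
the convention of the WHO premature-mortality indicator, and it is what
the per-category published series imply. Uncertainty intervals are a
Poisson parametric bootstrap on death counts (2.5th/97.5th percentiles);
the published series do not state their propagation method, so ours is
declared rather than claimed identical.

## Projection

**Bayesian model averaging.** The national indicator series (logit scale;
rates are modelled on the log scale) is regressed on every subset of ten
candidate covariates — the six risk-factor exposures plus wealth index,
years of schooling, urbanization and population — giving $2^{10} = 1024$
models. Model weights are marginal likelihoods under a conjugate
unit-information prior (Zellner $g$-prior, $g = n$) with a uniform prior
over models. For spaces too large to enumerate ($k > 20$) a Metropolis
sampler over model space (MC3) with 5000 burn-in and 20000 iterations
reproduces the weights to within ~0.02 total variation on small spaces
(tested). Predictions are the weight-averaged per-model conditional-MLE
fits; we deliberately do not shrink prediction coefficients by
$g/(1+g)$ because the module contract requires a noiseless linear truth to
extrapolate exactly, and the $n/(n+1)$ slope shrinkage is material 15
years beyond the data. Rank-deficient models get weight zero with a
warning. Predictive intervals come from seeded draws of the
model-mixture predictive distribution and widen with horizon distance.

**Spatiotemporal interpolation.** Survey exposures exist only at the
rounds (2005, 2009, 2011, 2016). A national linear trend is fit across all
provinces' observations; each province receives its mean residual as an
offset shrunk by $n_p/(n_p + \tau)$ ($\tau = 4$ by default, in
observation counts); observed province-years are reproduced exactly; and
years outside the observed range are back-cast/projected on the same
line. This is a deliberate simplification of full spatio-temporal
cascades, which the source methodology cites without equations.

**GP smoothing.** An optional Gaussian-process smoother (squared
exponential kernel, fixed hyperparameters, prior mean = data mean) is
available for exposure series; hyperparameters are configuration, not
optimized — reproducibility over flexibility.

**Covariates.** Wealth, schooling and urbanization are extended to the
horizon with an interpolating natural cubic spline, whose zero boundary
curvature makes tail extrapolation linear at the boundary slope;
urbanization is clamped to [0, 100].

**Mortality.** Per (sex, cause, age band, province), a Poisson log-linear
trend with a person-years offset is fit and extrapolated, with the
province slope shrunk toward the national slope by $D/(D+\tau)$
($D$ = stratum deaths, $\tau = 50$). Sub-national projected UPoD comes
from these rates; the national projection uses the BMA fit.

## Attributable fractions and scenarios

Prevalence exposures (diabetes, inactivity, smoking) use Levin's formula
$PAF = p(RR-1)/(p(RR-1)+1)$ and its potential-impact generalization
$PIF = (p - p^*)(RR-1)/(p(RR-1)+1)$. Continuous exposures (blood
pressure, BMI, salt) integrate a log-linear excess-risk curve
$RR(x) = RR_{unit}^{\max(0, x - m)}$ ($m$ = TMREL midpoint) over a normal
exposure distribution (trapezoid rule, 2001 points over $\pm 6$ SD) and
compare against a counterfactual distribution. The default counterfactual
is a point mass at the TMREL midpoint — this makes "population at the
TMREL" give a PAF of exactly zero, consistent with RR = 1 at TMREL; a
uniform-on-the-TMREL-interval option exists but yields small negative
fractions at the midpoint, which is why it is not the default. The exact
supplementary formulas of the source analysis are not public; these forms
are declared. Smoking is handled as current-smoking prevalence (the
impact-ratio refinement needs lung-cancer reference rates that have no
synthetic counterpart).

Joint fractions combine multiplicatively,
$PAF = 1 - \prod_i (1 - PAF_i)$, within (age, sex, cause, province)
cells; avoidable deaths are $PIF \times$ projected deaths per cell,
summed as requested — computing within cells before aggregating avoids
Simpson-type bias. Possible overlap between the salt and blood-pressure
cardiovascular pathways is not de-duplicated (the admissible-pair table
treats indirect pathways as direct pairs).

Scenario rules follow the WHO global monitoring framework: 25% relative
reduction for raised blood pressure, halt-at-baseline for diabetes and
obesity, 10% for inactivity, 30% for smoking, 30% for mean salt intake,
evaluated against a 2010 or 2015 baseline with a linear path in the
exposure metric from the baseline value to the horizon target (the
sources state only endpoint targets). Two decisions were genuinely open:

* *Blood-pressure target basis.* The framework states the target as a
  prevalence reduction while the exposure is a continuous mean. We reduce
  the excess of the mean over the TMREL midpoint
  ($x^* = m + (1-r)(x - m)$), a prevalence-of-raised-exposure style
  reduction expressed on the mean; salt reduces the mean itself because
  its target is explicitly about the population mean. The basis is
  configurable per risk.
* *Capping.* Counterfactual paths are capped at the projected path
  (`cap_at_projected = TRUE`): a reduction *target* never raises exposure
  above business-as-usual. Without the cap, risks whose baseline trend
  already beats the WHO target (smoking, salt) would produce negative
  impact fractions in some strata.

Achievement is flagged per (sex, cause, province) by
$q_{2030} \le \tfrac{2}{3} q_{baseline}$ — exact factor, `<=`, no
rounding.

## Life tables

Abridged tables use the same $a_x = n/2$ conversion, radix 100000, and
close at 70 for the 30--70 temporary life expectancy
$e_{30\text{-}70} = (T_{30} - T_{70})/l_{30} \le 40$. Cause deletion
defaults to Chiang's associated-single-decrement convention
$p^*_x = p_x^{1 - R_x}$ with $R_x$ the cause's share of band deaths; a
proportional-rates alternative $m^*_x = m_x(1 - R_x)$ is available (the
two agree closely for small $R$ and are both tested). The source names
only "the composition method" without equations, so the convention is
declared.

## The synthetic world

The generator's defaults are the stated conditions of the emulated
sources, fixed once:

* 31 provinces, registry years 2001--2015, horizon 2030, survey rounds
  2005/2009/2011/2016 with per-stratum sample size 1000.
* Cause-level 2015 indicator targets (by sex) at the magnitude of the
  published national 2015 estimates (e.g. cardiovascular $\approx$ 8.5%
  female / 10.1% male; all-four $\approx$ 14%), with annual log-rate
  slopes derived from the published 2010-to-2015 declines (about
  $-3$%/yr for cardiovascular disease, $-5.4$%/yr for cancers). The rate
  scale per cause and sex is solved numerically so the 2015 target is hit
  exactly in expectation.
* A Gompertz-like age gradient (log-rate increment 0.3--0.45 per 5-year
  band), mean-zero Gaussian province intercepts (SD 0.12) — the simplest
  exchangeable structure that produces sub-national heterogeneity — and
  Poisson noise on counts, the standard model for registry death counts.
* Exposure trends anchored at published 2015 levels with slopes matching
  the published 2010/2015/2030 pattern: rising diabetes, blood pressure,
  BMI and inactivity; falling smoking and salt (9.3/9.9 g/day female/male
  at 2015). Prevalences follow logistic trends (no ad hoc clipping);
  means are linear; survey noise is binomial/normal sampling error.
* Stylized population pyramid (3.25M down to 0.8M per sex per band across
  30--70) with 1.2%/yr growth; smooth monotone covariate trends.

What the generator does **not** emulate: registry incompleteness and
cause misclassification, changing provincial boundaries, definition drift
across survey rounds, age-group gaps in early rounds, or real
spatial correlation beyond exchangeable province effects. A green test
therefore establishes that the *methods* are implemented correctly and
recover known truth — not that the package reproduces any published
national estimate. The one published-magnitude check we run is loose by
design (the synthetic 2015 national UPoD within $\pm$30% of 14.7%, and
female temporary life expectancy within 10% of 39.62).

## Numerical choices

* Seeds are mandatory; every stochastic step draws from a stream derived
  from the master seed (FNV-1a hash of a stream label), so runs are
  byte-reproducible and streams are independent of evaluation order.
* Noise-off registry mode returns expected (possibly non-integer) counts
  so zero-noise identities hold exactly.
* PAF integration: fixed 2001-point trapezoid over mean $\pm 6$ SD;
  divergent integrands (RR overflow on the grid) are an error, not a
  silent Inf.
* Model ordering is lexicographic on the inclusion bitmask; ties in
  MC3 visit counting are impossible by construction (frequencies).
* Degenerate inputs error early with the offending stratum named
  (zero population, missing age bands, single survey round, inadmissible
  risk--cause pairs).

## Known limitations

The BMA response series is national (the source is ambiguous about
whether sub-national series entered the model averaging); province-level
projections rely on the log-linear mortality trend model. The
spatiotemporal model is a two-level shrinkage, not a full space-age-time
cascade. Exposures are age-invariant within 30--70 (surveys are emulated
as age-standardized); relative risks carry the age structure instead.
Avoidable deaths are allocated across age bands proportional to
age-specific PIF $\times$ deaths, as only totals are published.
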