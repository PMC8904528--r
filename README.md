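# ncdproj

Comparative-risk scenario analysis of premature mortality from
non-communicable diseases (NCDs), for epidemiologists and health-policy
analysts tracking SDG target 3.4 (a one-third reduction in premature NCD
mortality by 2030) at national and sub-national level.

The quantity at the centre of the package is the **unconditional
probability of dying between exact ages 30 and 70** (the WHO indicator
*₄₀q₃₀*, "UPoD"): with age-band rates *₅mₓ* = deaths / person-years
converted by *₅qₓ* = 5·₅mₓ / (1 + 2.5·₅mₓ),

> ₄₀q₃₀ = 1 − ∏ₓ (1 − ₅qₓ)  over the eight bands [30,35) … [65,70).

Around it the package implements:

* **Projection** to a horizon year: Bayesian model averaging over all
  2¹⁰ = 1024 subsets of ten candidate covariates (six risk-factor
  exposures + wealth, schooling, urbanization, population) with conjugate
  g-prior marginal likelihoods (exact enumeration, or MC3 with 5000
  burn-in / 20000 iterations for larger spaces); spatiotemporal
  interpolation of sparse survey rounds; Gaussian-process smoothing;
  natural-spline covariate extrapolation; Poisson log-linear sub-national
  mortality trends.
* **Attributable and avoidable deaths**: Levin PAFs and potential impact
  fractions for prevalence exposures, distributional integrals against
  TMREL counterfactuals for continuous exposures, multiplicative joint
  combination PAF = 1 − ∏(1 − PAFᵢ), and avoidable deaths under WHO-target
  (25% blood pressure, halt diabetes/obesity, 10% inactivity, 30% smoking,
  30% salt), theoretical-minimum (TMREL) and baseline scenarios.
* **Achievement classification** per sex × cause × province
  (horizon ≤ ⅔ × baseline, exact factor) and **life-expectancy gains**
  from cause-deleted abridged life tables (Chiang's p^(1−R) convention).
* A **synthetic-data module** that emulates a death-registration system
  (2001–2015, 31 provinces, Poisson counts around log-linear declining
  trends) and stepwise risk-factor surveys (rounds 2005/2009/2011/2016,
  rising metabolic risks, falling smoking and salt) with known ground
  truth, so the full pipeline is testable without restricted microdata.

See `vignettes/methods.Rmd` for the model, its assumptions, every tunable
parameter, and what a passing test does and does not establish.

## Worked example

Indicator with bootstrap uncertainty from a synthetic registry:

```r
library(ncdproj)
cfg <- sim_config(seed = 1)                     # 31 provinces, 2001-2015
reg <- generate_registry(cfg)
upod_uncertainty(reg, by = "year", draws = 200, seed = 1)
#    year   upod ui_low ui_high     (excerpt)
#    2010 0.1651 0.1641  0.1661
#    2015 0.1403 0.1394  0.1412
```

The four-category UPoD falls from 16.5% (2010) to 14.0% (2015) — the
synthetic world is calibrated to the magnitude of published national
estimates (17.5% and 14.7%), not to reproduce them.

Full pipeline under the WHO-target scenario on a smaller world:

```r
res <- run_pipeline(sim_config(n_provinces = 6, seed = 1),
                    scenario = "who2015")

res$upod_projected_national   # BMA projection, 2030:
#    sex  value ui_low ui_high
# female 0.0741 0.0619  0.0916
#   male 0.0837 0.0704  0.1043

res$achievement_summary       # provinces meeting SDG 3.4 (2015 baseline,
#    sex             cause n_achieved n_provinces     # after WHO cuts)
# female       asthma_COPD          4           6
#   male       asthma_COPD          3           6
# female           cancers          6           6
# ...
```

If current trends continue, the projected 2030 UPoD is 7.4% (women) and
8.4% (men). After applying the WHO risk-factor targets, every province
meets the one-third reduction for cancers and cardiovascular disease, but
asthma/COPD lags — the same qualitative pattern reported for real
national data. Joint avoidable deaths in 2030 sum to ≈5,200 (women) and
≈6,100 (men) in this 6-province world, and eliminating cardiovascular
deaths at the horizon would add 0.397 years of female life expectancy in
the 30–70 window (`res$life_expectancy`).

## Command line

```sh
inst/cli/ncdproj simulate --out data/ --seed 7
inst/cli/ncdproj upod --deaths data/registry.csv --by year,sex --out upod.csv
inst/cli/ncdproj run --preset who2015 --seed 7 --out results/
```

Subcommands: `simulate`, `upod`, `project`, `scenario`, `lifetable`,
`report`, `run`; common flags `--seed`, `--out`, `--log-level`. All
tables are long-format UTF-8 CSV with a `# ncdproj seed=… config=…`
metadata line.

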