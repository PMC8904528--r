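test_that("WHO target rules match the global monitoring framework", {
  spec <- who_target_rules(2015)
  expect_length(spec$rules, 6)
  expect_equal(spec$rules$smoking$fraction, 0.30)
  expect_equal(spec$rules$salt$fraction, 0.30)
  expect_equal(spec$rules$hypertension$fraction, 0.25)
  expect_equal(spec$rules$inactivity$fraction, 0.10)
  expect_equal(spec$rules$diabetes$rule, "halt_at_baseline")
  expect_equal(spec$rules$obesity$rule, "halt_at_baseline")
  expect_error(scenario_spec("x", 2015,
                             rules = list(vaping = list(rule = "none"))),
               "unknown risks")
  expect_error(scenario_spec("x", 2015,
                             rules = list(smoking = list(
                               rule = "relative_reduction", fraction = 2))),
               "fraction")
})

make_series <- function(values, years = 2010:2030, risk = "smoking",
                        metric = "prevalence") {
  data.frame(year = years, sex = "male", province = 1L, risk = risk,
             metric = metric, value = values, stringsAsFactors = FALSE)
}

test_that("counterfactual paths: none, halt, relative reduction", {
  yrs <- 2010:2030
  proj <- make_series(seq(0.30, 0.20, length.out = length(yrs)))
  none <- counterfactual_exposure(proj, preset_scenario("baseline"))
  expect_identical(none$value, proj$value)

  halt_spec <- scenario_spec("h", 2015, 2030,
                             list(smoking = list(rule = "halt_at_baseline")))
  halted <- counterfactual_exposure(proj, halt_spec, cap_at_projected = FALSE)
  base_val <- proj$value[proj$year == 2015]
  expect_equal(halted$value[halted$year == 2030], base_val)
  expect_equal(halted$value[halted$year == 2020], base_val)

  # 30% reduction on a 24.3% 2015 baseline lands at 17.01% in 2030
  proj2 <- make_series(rep(0.243, length(yrs)))
  red <- counterfactual_exposure(proj2, who_target_rules(2015))
  expect_equal(red$value[red$year == 2030], 0.7 * 0.243, tolerance = 1e-12)
  # linear path between baseline and horizon
  expect_equal(red$value[red$year == 2020],
               0.243 + (5 / 15) * (0.7 * 0.243 - 0.243), tolerance = 1e-12)
  # years before the baseline untouched
  expect_equal(red$value[red$year < 2015], rep(0.243, 5))
  expect_error(counterfactual_exposure(proj[proj$year > 2016, ],
                                       who_target_rules(2015)),
               "baseline year")
})

test_that("excess-basis reduction and TMREL rule for continuous risks", {
  yrs <- 2010:2030
  bp <- make_series(rep(128, length(yrs)), risk = "hypertension",
                    metric = "mean")
  red <- counterfactual_exposure(bp, who_target_rules(2015))
  # mid + 0.75 * (128 - 112.5)
  expect_equal(red$value[red$year == 2030], 112.5 + 0.75 * 15.5,
               tolerance = 1e-12)
  tm <- counterfactual_exposure(bp, preset_scenario("tmrel"))
  expect_equal(tm$value[tm$year == 2030], 112.5, tolerance = 1e-12)
})

test_that("cap keeps a reduction target below the projected path", {
  yrs <- 2010:2030
  # steeply falling projection that beats the WHO target
  proj <- make_series(seq(0.30, 0.05, length.out = length(yrs)))
  red <- counterfactual_exposure(proj, who_target_rules(2015))
  expect_true(all(red$value <= proj$value + 1e-12))
})

test_that("avoidable deaths scale with PIF and respect joint bounds", {
  cells <- expand.grid(sex = c("female", "male"), cause = "CVDs",
                       province = 1:2, age_lo = seq(30, 65, 5),
                       stringsAsFactors = FALSE)
  cells$deaths <- 100
  pifs <- do.call(rbind, lapply(c("smoking", "hypertension"), function(rk) {
    x <- cells[c("sex", "cause", "province", "age_lo")]
    x$risk <- rk
    x$age_hi <- x$age_lo + 5
    x$pif <- if (rk == "smoking") 0.2 else 0.3
    x
  }))
  av <- avoidable_deaths(cells, pifs)
  per_risk <- av[av$risk != "joint", ]
  expect_equal(per_risk$avoidable, per_risk$pif * 100)
  joint <- av[av$risk == "joint", ]
  expect_equal(joint$pif, rep(1 - 0.8 * 0.7, nrow(joint)), tolerance = 1e-12)
  # joint between max single and sum of singles
  expect_true(all(joint$avoidable >= 30 - 1e-9 &
                    joint$avoidable <= 50 + 1e-9))
  # PIF 0 / PIF 1 edge cases
  p0 <- pifs
  p0$pif <- 0
  expect_true(all(avoidable_deaths(cells, p0)$avoidable == 0))
  p1 <- pifs
  p1$pif <- 1
  av1 <- avoidable_deaths(cells, p1)
  expect_true(all(av1$avoidable[av1$risk == "joint"] == 100))
  pbad <- pifs
  pbad$pif[1] <- 1.4
  expect_error(avoidable_deaths(cells, pbad), "\\[0, 1\\]")
})

test_that("adjusted UPoD: identity at zero, zero at full avoidance", {
  cfg <- tiny_config()
  r <- generate_registry(cfg)
  surf <- r[r$year == 2015, ]
  pifs <- expand.grid(sex = c("female", "male"), cause = ncd_causes(),
                      province = 1:3, age_lo = seq(30, 65, 5),
                      stringsAsFactors = FALSE)
  pifs$risk <- "smoking"
  pifs$age_hi <- pifs$age_lo + 5
  pifs$pif <- 0
  av0 <- avoidable_deaths(surf, pifs)
  u0 <- adjusted_upod(surf, av0, by = "sex")
  expect_equal(u0$upod, upod_from_surface(surf, by = "sex")$upod,
               tolerance = 1e-12)
  pifs$pif <- 1
  av1 <- avoidable_deaths(surf, pifs)
  u1 <- adjusted_upod(surf, av1, by = "sex")
  expect_equal(u1$upod, c(0, 0), tolerance = 1e-12)
  pifs$pif <- 0.3
  av <- avoidable_deaths(surf, pifs)
  u <- adjusted_upod(surf, av, by = "sex")
  expect_true(all(u$upod < u0$upod))
  # inconsistent inputs rejected
  av_bad <- av1
  av_bad$avoidable <- av_bad$avoidable * 2 + 10
  expect_error(adjusted_upod(surf, av_bad), "exceed")
})

test_that("SDG flag logic reproduces the published baseline contrast", {
  expect_true(sdg_achievement(0.175, 0.108)$achieved)
  expect_false(sdg_achievement(0.147, 0.108)$achieved)
  expect_true(sdg_achievement(0.2, 0)$achieved)
  # boundary uses <= with the exact 2/3 factor (0.75 * 2/3 is float-exact)
  expect_true(sdg_achievement(0.75, 0.5)$achieved)
  expect_false(sdg_achievement(0.75, 0.5 + 1e-12)$achieved)
  expect_error(sdg_achievement(1.2, 0.5), "\\[0, 1\\]")
})

test_that("subnational summary counts match a brute-force recount", {
  set.seed(61)
  flags <- expand.grid(sex = c("female", "male"), cause = ncd_causes(),
                       province = 1:31, stringsAsFactors = FALSE)
  flags$achieved <- stats::runif(nrow(flags)) > 0.4
  s <- subnational_summary(flags)
  for (i in seq_len(nrow(s))) {
    manual <- sum(flags$achieved[flags$sex == s$sex[i] &
                                   flags$cause == s$cause[i]])
    expect_equal(s$n_achieved[i], manual)
    expect_lte(s$n_achieved[i], 31)
  }
  flags$achieved <- TRUE
  expect_true(all(subnational_summary(flags)$n_achieved == 31))
  flags$achieved <- FALSE
  expect_true(all(subnational_summary(flags)$n_achieved == 0))
})
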