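test_that("model enumeration is exhaustive and duplicate-free", {
  expect_equal(nrow(enumerate_models(1)), 2)
  expect_equal(nrow(enumerate_models(3)), 8)
  m <- enumerate_models(10)
  expect_equal(nrow(m), 1024)
  expect_equal(anyDuplicated(m), 0)
  # lexicographic on the inclusion bitmask: row i encodes i - 1
  ids <- as.integer(m %*% 2^(0:9))
  expect_equal(ids, 0:1023)
  expect_error(enumerate_models(21), "mc3")
  expect_error(enumerate_models(0), "at least 1")
})

test_that("bma_config validates its fields", {
  expect_error(bma_config(burn_in = 20000, iterations = 20000), "burn_in")
  expect_error(bma_config(covariate_labels = c("a", "a")), "unique")
  cfg <- bma_config()
  expect_equal(cfg$burn_in, 5000L)
  expect_equal(cfg$iterations, 20000L)
})

test_that("BMA identifies the generating covariate in the noiseless limit", {
  set.seed(101)
  n <- 30
  X <- matrix(stats::rnorm(3 * n), n, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- 1 + 2 * X[, 1] + stats::rnorm(n, 0, 1e-9)
  fit <- fit_bma(y, X, bma_config(covariate_labels = colnames(X), seed = 1))
  expect_gt(fit$pip["x1"], 0.99)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("pure-noise responses earn no confident inclusion", {
  set.seed(102)
  n <- 15
  worst <- replicate(50, {
    X <- matrix(stats::rnorm(3 * n), n, 3,
                dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- stats::rnorm(n)
    max(fit_bma(y, X,
                bma_config(covariate_labels = colnames(X), seed = 1))$pip)
  })
  # under the null, confident (>0.9) inclusion should be rare
  expect_lt(mean(worst > 0.9), 0.05)
})

test_that("MC3 weights agree with enumeration on a small space", {
  set.seed(103)
  n <- 40
  X <- matrix(stats::rnorm(5 * n), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- 1 + X[, 1] - 0.8 * X[, 4] + stats::rnorm(n, 0, 0.5)
  fe <- fit_bma(y, X, bma_config(covariate_labels = colnames(X),
                                 sampler = "enumerate", seed = 9))
  fm <- fit_bma(y, X, bma_config(covariate_labels = colnames(X),
                                 sampler = "mc3", seed = 9))
  key <- function(m) apply(m, 1, function(r) paste(as.integer(r),
                                                   collapse = ""))
  we <- stats::setNames(fe$weights, key(fe$models))
  wm <- stats::setNames(fm$weights, key(fm$models))
  allk <- union(names(we), names(wm))
  fill <- function(w) {
    v <- w[allk]
    v[is.na(v)] <- 0
    v
  }
  tv <- sum(abs(fill(we) - fill(wm))) / 2
  expect_lt(tv, 0.02)
})

test_that("single-model linear truth extrapolates exactly; intervals widen", {
  yrs <- 2001:2015
  X <- matrix(yrs, ncol = 1, dimnames = list(NULL, "year"))
  y <- 0.5 - 0.01 * (yrs - 2001)
  fit <- fit_bma(y, X, bma_config(covariate_labels = "year", seed = 2))
  newX <- matrix(c(2016, 2030), ncol = 1)
  pr <- project_bma(fit, newX)
  # noise-free linear truth: the covariate model takes all the weight and
  # per-model MLE coefficients extrapolate the line exactly
  truth <- 0.5 - 0.01 * (c(2016, 2030) - 2001)
  expect_equal(pr$value, truth, tolerance = 1e-8)
  expect_gt(pr$ui_high[2] - pr$ui_low[2], pr$ui_high[1] - pr$ui_low[1])
  expect_error(project_bma(fit, matrix(NA_real_, 1, 1)), "missing")
})

test_that("BMA recovers a -3%/yr log-trend at the horizon (median of reps)", {
  yrs <- 2001:2015
  errs <- with_seed_local <- sapply(1:40, function(i) {
    set.seed(200 + i)
    upod_true <- 0.15 * exp(-0.03 * (yrs - 2001))
    obs <- upod_true * exp(stats::rnorm(length(yrs), 0, 0.02))
    X <- cbind(year = yrs, noise = stats::rnorm(length(yrs)))
    fit <- fit_bma(log(obs), X,
                   bma_config(covariate_labels = colnames(X), seed = i))
    truth30 <- 0.15 * exp(-0.03 * (2030 - 2001))
    pr <- project_bma(fit, cbind(2030, 0), back_transform = exp)
    abs(pr$value - truth30) / truth30
  })
  expect_lt(stats::median(errs), 0.10)
})

test_that("spatiotemporal interpolation honours observations and linearity", {
  rounds <- c(2005, 2009, 2011, 2016)
  s <- expand.grid(year = rounds, province = 1:3, sex = "female",
                   risk = "salt", stringsAsFactors = FALSE)
  s$metric <- "mean"
  s$value <- 10 - 0.1 * (s$year - 2005)
  out <- spatiotemporal_interpolate(s, 2001:2030)
  # observed values reproduced exactly
  obs <- out[out$year %in% rounds, ]
  expect_equal(obs$value, 10 - 0.1 * (obs$year - 2005), tolerance = 1e-9)
  # linear truth: interior years on the line
  mid <- out[out$year %in% c(2007, 2013), ]
  expect_equal(mid$value, 10 - 0.1 * (mid$year - 2005), tolerance = 1e-6)
  expect_true(all(out$provenance[out$year < 2005 | out$year > 2016] ==
                    "projected"))
  # identical provinces collapse to the national interpolation
  expect_equal(out$value[out$province == 1], out$value[out$province == 2],
               tolerance = 1e-9)
  # single round is not interpolable
  expect_error(spatiotemporal_interpolate(s[s$year == 2005, ], 2001:2030),
               "one observed round")
})

test_that("provinces shrink toward the national trend", {
  rounds <- c(2005, 2009, 2011, 2016)
  s <- expand.grid(year = rounds, province = 1:4, sex = "male",
                   risk = "smoking", stringsAsFactors = FALSE)
  s$metric <- "prevalence"
  s$value <- 0.3 + ifelse(s$province == 1, 0.10, 0)
  out <- spatiotemporal_interpolate(s, 2020, tau = 4)
  v1 <- out$value[out$province == 1]
  v2 <- out$value[out$province == 2]
  # province 1 sits above the others but below its raw offset (shrinkage)
  expect_gt(v1, v2)
  expect_lt(v1, 0.4 - 1e-6)
})

test_that("GP smoother: interpolation, constancy, and the kernel oracle", {
  x <- c(1, 3, 5, 8, 10)
  y <- c(2.0, 2.5, 2.2, 3.0, 3.3)
  out <- gpr_smooth(x, y, x_out = x, amplitude = 1, length_scale = 3,
                    noise_sd = 1e-7)
  expect_equal(out$value, y, tolerance = 1e-4)
  const <- gpr_smooth(x, rep(4, 5), x_out = c(2, 50), amplitude = 1,
                      length_scale = 3, noise_sd = 0.1)
  expect_equal(const$value, c(4, 4), tolerance = 1e-9)
  # direct kernel-formula computation at an interior point
  amplitude <- 1.5
  ell <- 2.5
  sn <- 0.3
  k <- function(a, b) amplitude^2 * exp(-outer(a, b, `-`)^2 / (2 * ell^2))
  K <- k(x, x) + diag(sn^2 + 1e-10 * amplitude^2, 5)
  xs <- 6
  manual <- mean(y) + k(xs, x) %*% solve(K, y - mean(y))
  pkg <- gpr_smooth(x, y, x_out = xs, amplitude = amplitude,
                    length_scale = ell, noise_sd = sn)
  expect_equal(pkg$value, as.numeric(manual), tolerance = 1e-10)
  expect_error(gpr_smooth(x, y, amplitude = -1), "positive")
  expect_error(gpr_smooth(x[1:2], y[1:2]), "3 points")
})

test_that("spline extrapolation is linear beyond the last knot", {
  cv <- data.frame(year = 2001:2015, province = 1,
                   covariate = "years_schooling", value = NA)
  cv$value <- 5 + 0.2 * (cv$year - 2001)
  out <- spline_extrapolate(cv, 2030)
  expect_equal(out$value, 5 + 0.2 * (out$year - 2001), tolerance = 1e-9)
  expect_equal(out$value[out$year %in% 2001:2015],
               cv$value, tolerance = 1e-12)
  # quadratic input: tail continues with the boundary derivative of the
  # fitted natural spline
  cv2 <- cv
  cv2$value <- (cv2$year - 2001)^2 / 10
  out2 <- spline_extrapolate(cv2, 2030)
  f <- stats::splinefun(cv2$year, cv2$value, method = "natural")
  slope <- (f(2015) - f(2015 - 1e-6)) / 1e-6
  tail_years <- 2016:2030
  expect_equal(out2$value[match(tail_years, out2$year)],
               f(2015) + slope * (tail_years - 2015), tolerance = 1e-4)
  expect_error(spline_extrapolate(cv[1:3, ], 2030), "4 observed")
})

test_that("mortality projection: flat truth, recovery, aggregation", {
  tr <- ncdproj:::default_registry_trends(all_causes())
  tr$slope <- 0
  cfg <- tiny_config(registry_noise = FALSE, registry_trends = tr,
                     province_sd = 0)
  r <- generate_registry(cfg)
  pm <- project_mortality(r, horizon_year = 2030, years = 2030)
  obs_mean <- r$deaths[r$year == 2015] / r$population[r$year == 2015]
  key_r <- paste(r$sex, r$cause, r$age_lo, r$province)[r$year == 2015]
  key_p <- paste(pm$sex, pm$cause, pm$age_lo, pm$province)
  expect_equal(pm$rate, obs_mean[match(key_p, key_r)], tolerance = 1e-6)

  # -2%/yr log-trend recovered within 15% relative error (median over reps)
  errs <- sapply(1:25, function(i) {
    tr2 <- tr
    tr2$slope <- -0.02
    cfgn <- tiny_config(seed = 300 + i, registry_trends = tr2)
    rn <- generate_registry(cfgn)
    pmn <- project_mortality(rn, horizon_year = 2030, years = 2030)
    sub <- pmn[pmn$cause == "CVDs" & pmn$sex == "male" & pmn$age_lo == 50, ]
    truth <- ncdproj:::true_rates(cfgn, ground_truth(cfgn), "CVDs", "male",
                                  1, 2030)[5]
    abs(sub$rate[sub$province == 1] - truth) / truth
  })
  expect_lt(stats::median(errs), 0.15)

  # national projection ~ population-weighted province projections
  cfg2 <- tiny_config(seed = 55)
  r2 <- generate_registry(cfg2)
  pm2 <- project_mortality(r2, horizon_year = 2030, years = 2030)
  truth2 <- ground_truth(cfg2)
  nat <- r2
  nat$province <- 1L
  agg <- aggregate(deaths ~ year + sex + cause + age_lo, data = r2, sum)
  popagg <- aggregate(population ~ year + sex + age_lo + province,
                      data = r2[r2$cause == "cancers", ], `[`, 1)
  share <- truth2$population$share
  sub <- pm2[pm2$cause == "CVDs" & pm2$sex == "female" & pm2$age_lo == 50, ]
  weighted <- sum(sub$rate * share) / sum(share)
  nat_fit <- stats::glm(deaths ~ I(year - 2001),
                        offset = log(population),
                        family = stats::poisson(),
                        data = aggregate(cbind(deaths, population) ~ year,
                                         data = r2[r2$cause == "CVDs" &
                                                     r2$sex == "female" &
                                                     r2$age_lo == 50, ],
                                         sum))
  nat_rate <- exp(sum(stats::coef(nat_fit) * c(1, 2030 - 2001)))
  expect_equal(weighted, nat_rate, tolerance = 0.05)

  # all-zero stratum projects zero with a warning
  r3 <- r2
  r3$deaths[r3$cause == "diabetes_mellitus" & r3$province == 2] <- 0
  expect_warning(pm3 <- project_mortality(r3, horizon_year = 2030,
                                          years = 2030), "all-zero")
  expect_true(all(pm3$rate[pm3$cause == "diabetes_mellitus" &
                             pm3$province == 2] == 0))
  expect_error(project_mortality(r2[r2$year < 2006, ], 2030), "8 observed")
})
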