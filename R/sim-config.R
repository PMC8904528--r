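#' Simulation configuration for the synthetic data generators
#'
#' Describes the world the generators emulate: a sub-nationally stratified
#' death-registration system observed 2001--2015 with log-linearly declining
#' cause-specific mortality, stepwise risk-factor surveys at four rounds
#' (2005, 2009, 2011, 2016) with rising diabetes / blood-pressure / BMI /
#' inactivity and falling smoking / salt, smooth covariate trends, and a
#' population projected to the horizon year. Defaults are calibrated so that
#' the synthetic 2015 national indicator levels are of the same magnitude as
#' published national estimates (four-category 40q30 near 15%).
#'
#' @param n_provinces Number of sub-national units (default 31).
#' @param years Observed registry years (default 2001:2015).
#' @param horizon_year Projection horizon (default 2030).
#' @param age_lo Lower bounds of contiguous 5-year age bands
#'   (default `seq(30, 65, 5)`, the eight bands of the 30--70 indicator).
#' @param causes Cause labels; the first four must be the NCD categories.
#' @param risks Risk-factor labels (default the six of
#'   [risk_factor_specs()]).
#' @param survey_years Survey round years (default `c(2005, 2009, 2011, 2016)`).
#' @param survey_n Per-stratum survey sample size controlling sampling noise.
#' @param registry_noise,survey_noise,covariate_noise Logical switches;
#'   `FALSE` yields expected values exactly (registry death counts are then
#'   possibly non-integer expectations).
#' @param province_sd Standard deviation of the mean-zero Gaussian province
#'   intercepts on the log-rate scale.
#' @param seed Master integer seed; every generator draws from a stream
#'   derived from it. Mandatory, no hidden global randomness.
#' @param registry_trends,survey_trends Optional data.frames overriding the
#'   default trend parameters (same columns as the defaults; see
#'   [ground_truth()]).
#' @return An object of class `ncd_sim_config`.
#' @export
sim_config <- function(n_provinces = 31,
                       years = 2001:2015,
                       horizon_year = 2030,
                       age_lo = seq(30, 65, by = 5),
                       causes = all_causes(),
                       risks = risk_names(),
                       survey_years = c(2005, 2009, 2011, 2016),
                       survey_n = 1000,
                       registry_noise = TRUE,
                       survey_noise = TRUE,
                       covariate_noise = TRUE,
                       province_sd = 0.12,
                       seed = 1,
                       registry_trends = NULL,
                       survey_trends = NULL) {
  if (n_provinces < 1) stop("n_provinces must be positive")
  if (length(years) < 2) stop("need at least two observed years")
  if (horizon_year <= max(years)) stop("horizon_year must follow the observed years")
  widths <- diff(c(age_lo, age_lo[length(age_lo)] + 5))
  if (any(diff(age_lo) != 5)) stop("age bands must be contiguous 5-year bands")
  cfg <- list(
    n_provinces = as.integer(n_provinces),
    years = as.integer(years),
    horizon_year = as.integer(horizon_year),
    age_lo = age_lo,
    age_hi = age_lo + 5,
    causes = causes,
    risks = risks,
    survey_years = as.integer(survey_years),
    survey_n = survey_n,
    registry_noise = isTRUE(registry_noise),
    survey_noise = isTRUE(survey_noise),
    covariate_noise = isTRUE(covariate_noise),
    province_sd = province_sd,
    seed = as.integer(seed),
    registry_trends = registry_trends %||% default_registry_trends(causes),
    survey_trends = survey_trends %||% default_survey_trends(risks)
  )
  class(cfg) <- "ncd_sim_config"
  cfg
}

# Default cause-level trend parameters. q2015_* are the target national
# cause-specific 40q30 values at 2015 (magnitudes of the published 2015
# national estimates); slope is the annual log-rate trend; age_slope the
# log-rate increment per 5-year band.
default_registry_trends <- function(causes) {
  tab <- data.frame(
    cause = c("cancers", "CVDs", "asthma_COPD", "diabetes_mellitus", "other"),
    q2015_female = c(0.030, 0.085, 0.015, 0.0062, 0.020),
    q2015_male = c(0.034, 0.101, 0.016, 0.0055, 0.030),
    slope = c(-0.054, -0.030, -0.025, -0.031, -0.020),
    age_slope = c(0.30, 0.45, 0.45, 0.45, 0.35),
    stringsAsFactors = FALSE
  )
  missing <- setdiff(causes, tab$cause)
  if (length(missing) > 0) {
    stop("no default trends for causes: ", paste(missing, collapse = ", "),
         "; supply registry_trends")
  }
  tab[match(causes, tab$cause), , drop = FALSE]
}

# Default exposure trend parameters: level at 2015 (proportion for
# prevalence-type, natural units for continuous-mean risks) and annual slope
# (logit scale for prevalence, natural units for means). Levels/slopes are
# anchored to the published 2010/2015/2030 national pattern: rising
# diabetes, blood pressure, BMI and inactivity; falling smoking and salt
# (2015 salt means 9.3 g/day female, 9.9 g/day male).
default_survey_trends <- function(risks) {
  tab <- data.frame(
    risk = c("diabetes", "hypertension", "obesity", "inactivity",
             "smoking", "salt"),
    level2015_female = c(0.095, 126.0, 27.3, 0.586, 0.033, 9.3),
    level2015_male = c(0.079, 128.0, 25.6, 0.468, 0.243, 9.9),
    slope_female = c(0.0123, 0.30, 0.080, 0.0533, -0.0218, -0.0733),
    slope_male = c(0.0138, 0.25, 0.090, 0.0513, -0.0271, -0.1067),
    stringsAsFactors = FALSE
  )
  missing <- setdiff(risks, tab$risk)
  if (length(missing) > 0) {
    stop("no default trends for risks: ", paste(missing, collapse = ", "),
         "; supply survey_trends")
  }
  tab[match(risks, tab$risk), , drop = FALSE]
}

#' Ground truth underlying a simulation configuration
#'
#' Deterministically expands a configuration (and its seed) into the exact
#' trend parameters, province effects and population model used by every
#' generator, enabling parameter-recovery tests against known truth.
#'
#' @param config An `ncd_sim_config`.
#' @return A list with elements `registry` (per cause x sex: rate scale at
#'   2015, annual log slope, age shape), `province_effects` (matrix of
#'   log-rate intercepts, provinces x causes), `survey` (per risk x sex:
#'   level and slope), `survey_offsets` (province offsets per risk), and
#'   `population` (province shares, per-band national 2015 population per
#'   sex, annual growth factor).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "ncd_sim_config"))
  tr <- config$registry_trends
  nb <- length(config$age_lo)
  shape <- lapply(seq_len(nrow(tr)), function(i) {
    s <- exp(tr$age_slope[i] * (seq_len(nb) - (nb + 1) / 2))
    s / mean(s)
  })
  names(shape) <- tr$cause

  # per-sex national 2015 population by band (persons), a stylized
  # middle-income age pyramid over ages 30-70, and 1.2%/yr growth
  band_pop <- c(3.25, 2.95, 2.45, 2.05, 1.80, 1.50, 1.15, 0.80) * 1e6
  if (nb != 8) {
    band_pop <- rep(2e6 * 8 / nb, nb)
  }

  reg <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      q_target <- if (sx == "female") tr$q2015_female[i] else tr$q2015_male[i]
      k <- solve_rate_scale(q_target, shape[[i]])
      data.frame(cause = tr$cause[i], sex = sx, scale2015 = k,
                 slope = tr$slope[i], age_slope = tr$age_slope[i],
                 stringsAsFactors = FALSE)
    }))
  }))

  st <- config$survey_trends
  survey <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      data.frame(
        risk = st$risk[i], sex = sx,
        level2015 = if (sx == "female") st$level2015_female[i] else st$level2015_male[i],
        slope = if (sx == "female") st$slope_female[i] else st$slope_male[i],
        stringsAsFactors = FALSE
      )
    }))
  }))

  sp <- risk_factor_specs()
  offset_scale <- ifelse(sp$exposure_kind[match(config$risks, sp$risk)] ==
                           "prevalence", 0.15,
                         c(hypertension = 1.5, obesity = 0.40,
                           salt = 0.35)[config$risks])
  offset_scale[is.na(offset_scale)] <- 0.15

  with_seed(sub_seed(config$seed, "ground_truth"), {
    u <- matrix(stats::rnorm(config$n_provinces * length(config$causes),
                             sd = config$province_sd),
                nrow = config$n_provinces,
                dimnames = list(NULL, config$causes))
    u <- sweep(u, 2, colMeans(u))  # mean-zero by construction
    so <- matrix(stats::rnorm(config$n_provinces * length(config$risks)),
                 nrow = config$n_provinces,
                 dimnames = list(NULL, config$risks))
    so <- sweep(sweep(so, 2, colMeans(so)), 2, offset_scale, `*`)
    z <- stats::rnorm(config$n_provinces, sd = 0.5)
    share <- exp(z) / sum(exp(z))
    list(
      registry = reg,
      province_effects = u,
      survey = survey,
      survey_offsets = so,
      population = list(share = share, band_pop_2015 = band_pop,
                        growth = 1.012)
    )
  })
}

# Solve for k such that upod_30_70(k * shape) == q_target.
solve_rate_scale <- function(q_target, shape) {
  if (q_target <= 0) return(0)
  f <- function(k) upod_30_70(k * shape) - q_target
  stats::uniroot(f, c(1e-10, 1), tol = 1e-12)$root
}

# True age-band death rates for one (cause, sex, province, year).
true_rates <- function(config, truth, cause, sex, province, year) {
  r <- truth$registry
  row <- r[r$cause == cause & r$sex == sex, ]
  nb <- length(config$age_lo)
  shape <- exp(row$age_slope * (seq_len(nb) - (nb + 1) / 2))
  shape <- shape / mean(shape)
  u <- truth$province_effects[province, cause]
  row$scale2015 * shape * exp(row$slope * (year - 2015) + u)
}

# True population by band for one (sex, province, year).
true_population <- function(config, truth, province, year) {
  p <- truth$population
  p$band_pop_2015 * p$share[province] * p$growth^(year - 2015)
}

# True exposure level for one (risk, sex, province, year). Prevalence-type
# risks follow a logistic trend in year; continuous means a linear trend.
exposure_truth <- function(config, truth, risk, sex, province, year) {
  s <- truth$survey
  row <- s[s$risk == risk & s$sex == sex, ]
  off <- truth$survey_offsets[province, risk]
  sp <- risk_factor_specs()
  kind <- sp$exposure_kind[match(risk, sp$risk)]
  v <- if (kind == "prevalence") {
    inv_logit(logit(row$level2015) + row$slope * (year - 2015) + off)
  } else {
    row$level2015 + row$slope * (year - 2015) + off
  }
  unname(v)
}
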