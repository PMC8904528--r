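#' Generate a registry-style mortality surface
#'
#' Simulates death counts and person-years by year, sex, province, cause and
#' 5-year age band from the ground-truth rate model
#' `rate = scale * exp(slope * (year - 2015) + u_province) * age_shape`.
#' With `registry_noise = TRUE` counts are Poisson with mean
#' `population * rate`; otherwise the (possibly non-integer) expected counts
#' are returned exactly, which makes zero-noise identities testable.
#'
#' @param config An [sim_config()] object.
#' @return A long data.frame with columns `year`, `sex`, `province`,
#'   `cause`, `age_lo`, `age_hi`, `deaths`, `population`. Age intervals are
#'   half-open `[age_lo, age_hi)`.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "ncd_sim_config"))
  truth <- ground_truth(config)
  if (any(truth$population$band_pop_2015 <= 0)) {
    stop("population must be strictly positive")
  }
  grid <- expand.grid(
    age_lo = config$age_lo,
    cause = config$causes,
    province = seq_len(config$n_provinces),
    sex = c("female", "male"),
    year = config$years,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  nb <- length(config$age_lo)
  reg <- truth$registry
  key <- paste(reg$cause, reg$sex)
  shape_of <- function(a) {
    s <- exp(a * (seq_len(nb) - (nb + 1) / 2))
    s / mean(s)
  }
  shapes <- lapply(seq_len(nrow(reg)), function(i) shape_of(reg$age_slope[i]))
  idx <- match(paste(grid$cause, grid$sex), key)
  band <- match(grid$age_lo, config$age_lo)
  scale <- reg$scale2015[idx]
  slope <- reg$slope[idx]
  shp <- vapply(seq_len(nrow(grid)),
                function(i) shapes[[idx[i]]][band[i]], numeric(1))
  u <- truth$province_effects[cbind(grid$province,
                                    match(grid$cause, config$causes))]
  rate <- scale * shp * exp(slope * (grid$year - 2015) + u)

  pop_nat <- truth$population$band_pop_2015[band] *
    truth$population$growth^(grid$year - 2015)
  population <- pop_nat * truth$population$share[grid$province]

  mu <- population * rate
  deaths <- if (config$registry_noise) {
    with_seed(sub_seed(config$seed, "registry"),
              stats::rpois(length(mu), mu))
  } else {
    mu
  }
  out <- data.frame(
    year = grid$year, sex = grid$sex, province = grid$province,
    cause = grid$cause, age_lo = grid$age_lo, age_hi = grid$age_lo + 5,
    deaths = deaths, population = population,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mortality_surface", "data.frame")
  out
}

#' Generate survey-style exposure series
#'
#' Simulates the sparse survey rounds: prevalence-type risks are binomial
#' draws of size `survey_n` around logistic time trends; continuous-mean
#' risks are normal draws around linear trends with standard error
#' `pop_sd / sqrt(survey_n)`. Years between rounds are absent by design
#' (interpolation is a downstream concern).
#'
#' @param config An [sim_config()] object.
#' @return A long data.frame with columns `year`, `sex`, `province`,
#'   `risk`, `metric` (`"prevalence"` or `"mean"`), `value`, `se`.
#' @export
generate_surveys <- function(config) {
  stopifnot(inherits(config, "ncd_sim_config"))
  truth <- ground_truth(config)
  sp <- risk_factor_specs()
  grid <- expand.grid(
    risk = config$risks,
    province = seq_len(config$n_provinces),
    sex = c("female", "male"),
    year = config$survey_years,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  kind <- sp$exposure_kind[match(grid$risk, sp$risk)]
  pop_sd <- sp$pop_sd[match(grid$risk, sp$risk)]
  tv <- vapply(seq_len(nrow(grid)), function(i) {
    exposure_truth(config, truth, grid$risk[i], grid$sex[i],
                   grid$province[i], grid$year[i])
  }, numeric(1))
  n <- config$survey_n
  value <- tv
  is_prev <- kind == "prevalence"
  se <- numeric(nrow(grid))
  se[is_prev] <- sqrt(tv[is_prev] * (1 - tv[is_prev]) / n)
  se[!is_prev] <- pop_sd[!is_prev] / sqrt(n)
  if (config$survey_noise) {
    value <- with_seed(sub_seed(config$seed, "surveys"), {
      v <- tv
      v[is_prev] <- stats::rbinom(sum(is_prev), n, tv[is_prev]) / n
      v[!is_prev] <- stats::rnorm(sum(!is_prev), tv[!is_prev],
                                  pop_sd[!is_prev] / sqrt(n))
      v
    })
  }
  out <- data.frame(
    year = grid$year, sex = grid$sex, province = grid$province,
    risk = grid$risk,
    metric = ifelse(kind == "prevalence", "prevalence", "mean"),
    value = value, se = se, stringsAsFactors = FALSE
  )
  class(out) <- c("exposure_series", "data.frame")
  out
}

#' Generate a synthetic relative-risk table
#'
#' Produces stand-in relative risks per risk--cause--age--sex cell,
#' restricted to the admissible pairs of [risk_cause_pairs()]. Prevalence
#' risks get categorical RRs (exposed vs unexposed); continuous-mean risks
#' get per-unit RRs applied to exposure above the TMREL midpoint. Log-RRs
#' attenuate with age, the usual pattern for metabolic and behavioural
#' risks. All RRs are >= 1 above TMREL and exactly 1 at TMREL by
#' construction of the per-unit form.
#'
#' @param config An [sim_config()] object.
#' @param pairs Optional data.frame of (risk, cause) pairs to generate;
#'   defaults to all admissible pairs. Pairs outside [risk_cause_pairs()]
#'   are rejected.
#' @return A data.frame with columns `risk`, `cause`, `sex`, `age_lo`,
#'   `age_hi`, `kind` (`"categorical"` or `"per_unit"`), `rr`.
#' @export
generate_rr_table <- function(config, pairs = NULL) {
  stopifnot(inherits(config, "ncd_sim_config"))
  admissible <- risk_cause_pairs()
  pairs <- pairs %||% admissible[admissible$risk %in% config$risks &
                                   admissible$cause %in% config$causes, ]
  ok <- paste(pairs$risk, pairs$cause) %in%
    paste(admissible$risk, admissible$cause)
  if (!all(ok)) {
    stop("inadmissible risk-cause pair(s): ",
         paste(paste(pairs$risk[!ok], pairs$cause[!ok], sep = "-"),
               collapse = ", "))
  }
  base_rr <- c(
    "diabetes.diabetes_mellitus" = 4.0, "diabetes.CVDs" = 1.8,
    "hypertension.CVDs" = 1.030, "hypertension.asthma_COPD" = 1.005,
    "obesity.cancers" = 1.010, "obesity.CVDs" = 1.025,
    "obesity.diabetes_mellitus" = 1.060,
    "inactivity.cancers" = 1.20, "inactivity.CVDs" = 1.40,
    "inactivity.diabetes_mellitus" = 1.50,
    "smoking.cancers" = 2.20, "smoking.CVDs" = 1.80,
    "smoking.asthma_COPD" = 2.50, "smoking.diabetes_mellitus" = 1.30,
    "salt.cancers" = 1.020, "salt.CVDs" = 1.025, "salt.asthma_COPD" = 1.010
  )
  sp <- risk_factor_specs()
  nb <- length(config$age_lo)
  age_factor <- seq(1.3, 0.6, length.out = nb)
  grid <- expand.grid(
    age_band = seq_len(nb),
    sex = c("female", "male"),
    pair = seq_len(nrow(pairs)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  risk <- pairs$risk[grid$pair]
  cause <- pairs$cause[grid$pair]
  kind <- ifelse(sp$exposure_kind[match(risk, sp$risk)] == "prevalence",
                 "categorical", "per_unit")
  b <- base_rr[paste(risk, cause, sep = ".")]
  if (anyNA(b)) stop("no base RR for some pair")
  rr <- exp(log(b) * age_factor[grid$age_band])
  out <- data.frame(
    risk = risk, cause = cause, sex = grid$sex,
    age_lo = config$age_lo[grid$age_band],
    age_hi = config$age_lo[grid$age_band] + 5,
    kind = kind, rr = rr, stringsAsFactors = FALSE
  )
  class(out) <- c("rr_table", "data.frame")
  out
}

#' Generate covariate series
#'
#' Smooth, monotone province-level trends for wealth index (0--1), years of
#' schooling and urbanization percentage (clamped to \[0, 100\]) over the
#' observed years, plus total population per province projected through the
#' horizon year. Small Gaussian noise is added when `covariate_noise = TRUE`.
#'
#' @param config An [sim_config()] object.
#' @return A data.frame with columns `year`, `province`, `covariate`,
#'   `value`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "ncd_sim_config"))
  truth <- ground_truth(config)
  yrs <- config$years
  P <- config$n_provinces
  base <- expand.grid(year = yrs, province = seq_len(P),
                      KEEP.OUT.ATTRS = FALSE)
  t <- base$year - 2015
  prov_shift <- (base$province - (P + 1) / 2) / max(P, 2)
  wealth <- pmin(pmax(0.55 + 0.012 * t + 0.10 * prov_shift, 0), 1)
  school <- pmax(8.8 + 0.11 * t + 1.0 * prov_shift, 0)
  urban <- pmin(pmax(71 + 0.55 * t + 8 * prov_shift, 0), 100)
  obs <- rbind(
    data.frame(base, covariate = "wealth_index", value = wealth),
    data.frame(base, covariate = "years_schooling", value = school),
    data.frame(base, covariate = "urbanization", value = urban)
  )
  if (config$covariate_noise) {
    scale <- c(wealth_index = 0.004, years_schooling = 0.04,
               urbanization = 0.20)[obs$covariate]
    obs$value <- with_seed(sub_seed(config$seed, "covariates"),
                           obs$value + stats::rnorm(nrow(obs), 0, scale))
    obs$value[obs$covariate == "wealth_index"] <-
      pmin(pmax(obs$value[obs$covariate == "wealth_index"], 0), 1)
    obs$value[obs$covariate == "urbanization"] <-
      pmin(pmax(obs$value[obs$covariate == "urbanization"], 0), 100)
  }
  pop_years <- seq(min(yrs), config$horizon_year)
  popg <- expand.grid(year = pop_years, province = seq_len(P),
                      KEEP.OUT.ATTRS = FALSE)
  pop_total <- sum(truth$population$band_pop_2015) * 2  # both sexes
  popg$covariate <- "population"
  popg$value <- pop_total * truth$population$share[popg$province] *
    truth$population$growth^(popg$year - 2015)
  out <- rbind(obs[c("year", "province", "covariate", "value")], popg)
  out <- out[order(out$covariate, out$province, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("covariate_series", "data.frame")
  out
}

#' Write synthetic inputs to a directory of CSV files
#'
#' @param config An [sim_config()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`registry.csv`, `surveys.csv`,
#'   `rr.csv`, `covariates.csv`).
#' @export
write_synthetic_inputs <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(
    registry = generate_registry(config),
    surveys = generate_surveys(config),
    rr = generate_rr_table(config),
    covariates = generate_covariates(config)
  )
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_ncd_csv(tabs[[nm]], p, seed = config$seed, config = config)
    p
  }, character(1))
  invisible(paths)
}
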