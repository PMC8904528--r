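# CSV dialect: long-format UTF-8 with a header row, one leading comment
# line carrying run metadata (seed + config fingerprint), missing values
# as empty fields. Read back with read_ncd_csv().

#' Write/read the package CSV dialect
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @param seed Seed recorded in the metadata comment line.
#' @param config Optional object fingerprinted into the metadata line.
#' @return `write_ncd_csv`: invisibly, `path`; `read_ncd_csv`: a
#'   data.frame.
#' @export
write_ncd_csv <- function(x, path, seed = NA, config = NULL) {
  meta <- sprintf("# ncdproj seed=%s config=%s", seed,
                  if (is.null(config)) "none"
                  else format(fnv1a(paste(deparse(unclass(config)),
                                          collapse = ""))))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, qmethod = "double",
                     na = "")
  invisible(path)
}

#' @rdname write_ncd_csv
#' @export
read_ncd_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate pipeline input tables
#'
#' Checks the registry, survey, relative-risk and covariate dialects:
#' required headers, age-band contiguity, non-negative deaths and positive
#' population, prevalences inside \[0, 1\], RR positivity and risk--cause
#' pair admissibility. Returns one row per problem; a clean input yields a
#' zero-row report.
#'
#' @param registry,surveys,rr,covariates Optional data.frames in the
#'   dialects of the corresponding generators; omitted tables are skipped.
#' @return A data.frame `table`, `row`, `problem` (zero rows when clean).
#' @export
validate_inputs <- function(registry = NULL, surveys = NULL, rr = NULL,
                            covariates = NULL) {
  issues <- list()
  flag <- function(table, row, problem) {
    issues[[length(issues) + 1]] <<- data.frame(
      table = table, row = row, problem = problem, stringsAsFactors = FALSE)
  }
  if (!is.null(registry)) {
    need <- c("year", "sex", "province", "cause", "age_lo", "age_hi",
              "deaths", "population")
    if (!all(need %in% names(registry))) {
      flag("registry", NA, paste("missing columns:",
           paste(setdiff(need, names(registry)), collapse = ", ")))
    } else {
      bad <- which(registry$deaths < 0)
      for (i in bad) flag("registry", i, "negative deaths")
      bad <- which(!(registry$population > 0))
      for (i in bad) flag("registry", i, "non-positive population")
      bad <- which(registry$age_hi <= registry$age_lo)
      for (i in bad) flag("registry", i, "age_hi <= age_lo")
      ages <- sort(unique(registry$age_lo))
      if (length(ages) > 1 && any(diff(ages) !=
            (registry$age_hi - registry$age_lo)[match(ages[-length(ages)],
                                                      registry$age_lo)])) {
        flag("registry", NA, "age bands not contiguous")
      }
    }
  }
  if (!is.null(surveys)) {
    need <- c("year", "sex", "province", "risk", "metric", "value", "se")
    if (!all(need %in% names(surveys))) {
      flag("surveys", NA, paste("missing columns:",
           paste(setdiff(need, names(surveys)), collapse = ", ")))
    } else {
      bad <- which(surveys$metric == "prevalence" &
                     (surveys$value < 0 | surveys$value > 1))
      for (i in bad) flag("surveys", i, "prevalence outside [0, 1]")
    }
  }
  if (!is.null(rr)) {
    need <- c("risk", "cause", "sex", "age_lo", "age_hi", "kind", "rr")
    if (!all(need %in% names(rr))) {
      flag("rr", NA, paste("missing columns:",
           paste(setdiff(need, names(rr)), collapse = ", ")))
    } else {
      bad <- which(!(rr$rr > 0))
      for (i in bad) flag("rr", i, "non-positive RR")
      adm <- paste(risk_cause_pairs()$risk, risk_cause_pairs()$cause)
      bad <- which(!(paste(rr$risk, rr$cause) %in% adm))
      for (i in bad) {
        flag("rr", i, paste0("inadmissible risk-cause pair: ", rr$risk[i],
                             "-", rr$cause[i]))
      }
    }
  }
  if (!is.null(covariates)) {
    need <- c("year", "province", "covariate", "value")
    if (!all(need %in% names(covariates))) {
      flag("covariates", NA, paste("missing columns:",
           paste(setdiff(need, names(covariates)), collapse = ", ")))
    } else {
      bad <- which(covariates$covariate == "urbanization" &
                     (covariates$value < 0 | covariates$value > 100))
      for (i in bad) flag("covariates", i, "urbanization outside [0, 100]")
    }
  }
  if (length(issues) == 0) {
    return(data.frame(table = character(0), row = integer(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

# National per-sex exposure series averaged over provinces
# (population-share weights would need the covariates; provinces are
# near-exchangeable in the synthetic world, so the simple mean suffices).
national_exposure <- function(exposures) {
  grp <- interaction(exposures$year, exposures$sex, exposures$risk,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(exposures, grp), function(g) {
    data.frame(year = g$year[1], sex = g$sex[1], risk = g$risk[1],
               metric = g$metric[1], value = mean(g$value),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full scenario-analysis pipeline
#'
#' Orchestrates, on synthetic inputs generated from `config`:
#' simulate -> observed UPoD by year/sex -> exposure interpolation and
#' projection to the horizon -> covariate spline extrapolation -> national
#' BMA projection of UPoD (ten candidate covariates) -> sub-national
#' log-linear mortality projection -> scenario counterfactuals, potential
#' impact fractions and avoidable deaths -> UPoD recomputed after removing
#' avoidable deaths -> SDG 3.4 achievement flags per sex, cause and
#' province -> temporary life expectancy 30--70 and cause-deleted gains.
#' The `baseline` preset skips the counterfactual stages (no
#' avoidable-death tables).
#'
#' @param config An [sim_config()].
#' @param scenario Preset name (see [preset_scenario()]) or a
#'   `scenario_spec`.
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV with a metadata line carrying the seed and a config
#'   fingerprint.
#' @param bma_draws Predictive draws for BMA intervals.
#' @return A named list of result tables: `upod_observed`,
#'   `upod_projected_national`, `upod_projected_province`,
#'   `exposures_projected`, and for intervention scenarios
#'   `exposures_counterfactual`, `pifs`, `avoidable`, `upod_adjusted`,
#'   `achievement`, `achievement_summary`, plus `life_expectancy` and
#'   `metadata`.
#' @export
run_pipeline <- function(config = sim_config(), scenario = "who2015",
                         out_dir = NULL, bma_draws = 500) {
  spec <- if (inherits(scenario, "scenario_spec")) scenario
          else preset_scenario(scenario, horizon_year = config$horizon_year)
  h <- config$horizon_year
  registry <- generate_registry(config)
  surveys <- generate_surveys(config)
  rr <- generate_rr_table(config)
  covariates <- generate_covariates(config)
  rep_issues <- validate_inputs(registry, surveys, rr, covariates)
  if (nrow(rep_issues) > 0) {
    stop("stage validate_inputs: synthetic inputs failed validation (",
         nrow(rep_issues), " issue(s))")
  }

  upod_obs <- upod_from_surface(registry, by = c("year", "sex"))

  # exposures: interpolate sparse rounds over the full span, then GP-smooth
  all_years <- seq(min(config$years), h)
  exp_interp <- spatiotemporal_interpolate(surveys, all_years)
  nat_exp <- national_exposure(exp_interp)

  cov_proj <- spline_extrapolate(covariates, h)

  # national covariate matrix by year: 6 risks (per sex) + 4 covariates
  nat_cov <- do.call(rbind, lapply(split(cov_proj,
                                         list(cov_proj$covariate,
                                              cov_proj$year), drop = TRUE),
    function(g) data.frame(year = g$year[1], covariate = g$covariate[1],
                           value = mean(g$value))))
  build_X <- function(sex, years_wanted) {
    cols <- lapply(covariate_labels(), function(cv) {
      if (cv %in% risk_names()) {
        d <- nat_exp[nat_exp$risk == cv & nat_exp$sex == sex, ]
        d$value[match(years_wanted, d$year)]
      } else {
        d <- nat_cov[nat_cov$covariate == cv, ]
        d$value[match(years_wanted, d$year)]
      }
    })
    X <- do.call(cbind, cols)
    colnames(X) <- covariate_labels()
    X
  }

  # national BMA projection of UPoD (logit scale) per sex
  bcfg <- bma_config(seed = config$seed)
  upod_nat <- do.call(rbind, lapply(c("female", "male"), function(sx) {
    obs <- upod_obs[upod_obs$sex == sx, ]
    Xo <- build_X(sx, obs$year)
    fit <- fit_bma(logit(obs$upod), Xo, bcfg)
    Xn <- build_X(sx, all_years)
    pr <- project_bma(fit, Xn, draws = bma_draws,
                      back_transform = inv_logit)
    data.frame(year = all_years, sex = sx, pr,
               provenance = ifelse(all_years %in% obs$year, "observed",
                                   "projected"),
               stringsAsFactors = FALSE)
  }))

  # sub-national mortality projection and horizon surface
  mort_proj <- project_mortality(registry, horizon_year = h, years = h)
  truth <- ground_truth(config)
  horizon_surface <- mort_proj
  pop <- vapply(seq_len(nrow(mort_proj)), function(i) {
    true_population(config, truth, mort_proj$province[i],
                    h)[match(mort_proj$age_lo[i], config$age_lo)]
  }, numeric(1))
  horizon_surface$population <- pop
  horizon_surface$deaths <- horizon_surface$rate * pop
  horizon_surface$rate <- NULL

  upod_prov_h <- upod_from_surface(horizon_surface,
                                   by = c("sex", "province"))
  upod_cause_h <- do.call(rbind, lapply(ncd_causes(), function(cz) {
    u <- upod_from_surface(horizon_surface, causes = cz,
                           by = c("sex", "province"))
    u$cause <- cz
    u
  }))
  upod_base_prov <- do.call(rbind, lapply(ncd_causes(), function(cz) {
    u <- upod_from_surface(
      registry[registry$year == spec$baseline_year, ], causes = cz,
      by = c("sex", "province"))
    u$cause <- cz
    u
  }))

  results <- list(
    upod_observed = upod_obs,
    upod_projected_national = upod_nat,
    upod_projected_province = upod_prov_h,
    exposures_projected = exp_interp
  )

  intervention <- any(vapply(spec$rules, function(r) r$rule != "none",
                             logical(1)))
  if (intervention) {
    exp_cf <- counterfactual_exposure(exp_interp, spec)
    pifs <- compute_pifs(exp_interp, exp_cf, rr, year = h)
    avoid <- avoidable_deaths(horizon_surface, pifs)
    upod_adj <- do.call(rbind, lapply(ncd_causes(), function(cz) {
      u <- adjusted_upod(horizon_surface, avoid, by = c("sex", "province"),
                         causes = cz)
      u$cause <- cz
      u
    }))
    bk <- paste(upod_base_prov$sex, upod_base_prov$province,
                upod_base_prov$cause)
    base_match <- upod_base_prov$upod[
      match(paste(upod_adj$sex, upod_adj$province, upod_adj$cause), bk)]
    flags <- cbind(upod_adj[c("sex", "province", "cause")],
                   sdg_achievement(base_match, upod_adj$upod))
    results$exposures_counterfactual <- exp_cf
    results$pifs <- pifs
    results$avoidable <- avoid
    results$upod_adjusted <- upod_adj
    results$achievement <- flags
    results$achievement_summary <- subnational_summary(flags)
    le_surface <- adjusted_surface(horizon_surface, avoid)
  } else {
    bk <- paste(upod_base_prov$sex, upod_base_prov$province,
                upod_base_prov$cause)
    base_match <- upod_base_prov$upod[
      match(paste(upod_cause_h$sex, upod_cause_h$province,
                  upod_cause_h$cause), bk)]
    flags <- cbind(upod_cause_h[c("sex", "province", "cause")],
                   sdg_achievement(base_match, upod_cause_h$upod))
    results$achievement <- flags
    results$achievement_summary <- subnational_summary(flags)
    le_surface <- horizon_surface
  }

  results$life_expectancy <- life_expectancy_tables(
    registry, le_surface, baseline_year = max(config$years))

  results$metadata <- data.frame(
    key = c("seed", "scenario", "baseline_year", "horizon_year",
            "n_provinces"),
    value = as.character(c(config$seed, spec$name, spec$baseline_year, h,
                           config$n_provinces)),
    stringsAsFactors = FALSE
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(results)) {
      write_ncd_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                    seed = config$seed, config = config)
    }
  }
  results
}

# Subtract joint avoidable deaths from a horizon surface.
adjusted_surface <- function(surface, avoidable) {
  av <- avoidable[avoidable$risk == "joint", ]
  key <- paste(surface$sex, surface$cause, surface$province,
               surface$age_lo)
  akey <- paste(av$sex, av$cause, av$province, av$age_lo)
  sub <- av$avoidable[match(key, akey)]
  sub[is.na(sub)] <- 0
  surface$deaths <- pmax(surface$deaths - sub, 0)
  surface
}

# Temporary life expectancy 30-70 at baseline and horizon, plus
# cause-deleted gains per NCD category, by sex (national, all causes).
life_expectancy_tables <- function(registry, horizon_surface,
                                   baseline_year) {
  one <- function(surface, yr_label, sx) {
    cell <- interaction(surface$age_lo, drop = TRUE)
    d <- surface[surface$sex == sx, ]
    # all-cause deaths per age band; population counted once per band
    pc <- interaction(d$province, d$age_lo, drop = TRUE)
    dd <- data.frame(
      age_lo = as.numeric(tapply(d$age_lo, pc, `[`, 1)),
      deaths = as.numeric(tapply(d$deaths, pc, sum)),
      population = as.numeric(tapply(d$population, pc, `[`, 1))
    )
    agg_d <- tapply(dd$deaths, dd$age_lo, sum)
    agg_p <- tapply(dd$population, dd$age_lo, sum)
    m <- as.numeric(agg_d / agg_p)
    ages <- as.numeric(names(agg_d))
    lt <- build_life_table(m, age_lo = ages)
    e <- temporary_life_expectancy(lt, 30, 70)
    gains <- vapply(ncd_causes(), function(cz) {
      dc <- d[d$cause == cz, ]
      cz_d <- tapply(dc$deaths, dc$age_lo, sum)
      R <- as.numeric(cz_d[names(agg_d)]) / as.numeric(agg_d)
      R[!is.finite(R)] <- 0
      le_gain(lt, R, 30, 70)
    }, numeric(1))
    data.frame(period = yr_label, sex = sx, e30_70 = e,
               cause = c(NA, ncd_causes()),
               gain = c(NA, gains), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(c("female", "male"), function(sx) {
      one(registry[registry$year == baseline_year, ],
          as.character(baseline_year), sx)
    }),
    lapply(c("female", "male"), function(sx) {
      one(horizon_surface, "horizon", sx)
    })
  ))
  rownames(out) <- NULL
  out
}
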