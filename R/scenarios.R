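#' Construct a scenario specification
#'
#' A scenario is a baseline year, a horizon year and one counterfactual
#' rule per risk factor: `relative_reduction` (fraction of the baseline
#' exposure removed by the horizon), `halt_at_baseline` (exposure frozen at
#' its baseline value), `to_tmrel` (exposure brought to the theoretical
#' minimum by the horizon) or `none`.
#'
#' @param name Scenario label.
#' @param baseline_year Comparison baseline (2010 or 2015 in the presets).
#' @param horizon_year Target year (default 2030).
#' @param rules Named list, one entry per risk: either `list(rule =
#'   "relative_reduction", fraction = r)` or `list(rule =
#'   "halt_at_baseline")` / `list(rule = "to_tmrel")` / `list(rule =
#'   "none")`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, baseline_year, horizon_year = 2030, rules) {
  known <- risk_names()
  if (!all(names(rules) %in% known)) {
    stop("rules for unknown risks: ",
         paste(setdiff(names(rules), known), collapse = ", "))
  }
  for (r in rules) {
    if (!r$rule %in% c("relative_reduction", "halt_at_baseline",
                       "to_tmrel", "none")) {
      stop("unknown rule: ", r$rule)
    }
    if (r$rule == "relative_reduction" &&
        (is.null(r$fraction) || r$fraction < 0 || r$fraction > 1)) {
      stop("relative_reduction requires a fraction in [0, 1]")
    }
  }
  structure(list(name = name, baseline_year = as.integer(baseline_year),
                 horizon_year = as.integer(horizon_year), rules = rules),
            class = "scenario_spec")
}

#' WHO global-monitoring-framework target rules
#'
#' The six risk-factor targets: 25% relative reduction for raised blood
#' pressure, halt the rise in diabetes and in obesity, 10% reduction in
#' physical inactivity, 30% reduction in current smoking, 30% reduction in
#' mean salt intake.
#'
#' @param baseline_year Baseline against which reductions are measured
#'   (2015 by default; 2010 gives the other published comparison).
#' @param horizon_year Target year (default 2030).
#' @return A `scenario_spec` named `who<baseline_year>`.
#' @export
who_target_rules <- function(baseline_year = 2015, horizon_year = 2030) {
  scenario_spec(
    name = paste0("who", baseline_year),
    baseline_year = baseline_year, horizon_year = horizon_year,
    rules = list(
      hypertension = list(rule = "relative_reduction", fraction = 0.25),
      diabetes = list(rule = "halt_at_baseline"),
      obesity = list(rule = "halt_at_baseline"),
      inactivity = list(rule = "relative_reduction", fraction = 0.10),
      smoking = list(rule = "relative_reduction", fraction = 0.30),
      salt = list(rule = "relative_reduction", fraction = 0.30)
    )
  )
}

#' Packaged scenario presets
#'
#' `"baseline"` (no intervention: all rules `none`), `"who2010"` /
#' `"who2015"` (WHO targets against either baseline), `"tmrel"` (all risks
#' to their theoretical minimum).
#'
#' @param preset Preset name.
#' @param horizon_year Target year (default 2030).
#' @return A `scenario_spec`.
#' @export
preset_scenario <- function(preset = c("baseline", "who2010", "who2015",
                                       "tmrel"),
                            horizon_year = 2030) {
  preset <- match.arg(preset)
  switch(preset,
    baseline = scenario_spec("baseline", 2015, horizon_year,
                             stats::setNames(rep(list(list(rule = "none")),
                                                 length(risk_names())),
                                             risk_names())),
    who2010 = who_target_rules(2010, horizon_year),
    who2015 = who_target_rules(2015, horizon_year),
    tmrel = scenario_spec("tmrel", 2015, horizon_year,
                          stats::setNames(rep(list(list(rule = "to_tmrel")),
                                              length(risk_names())),
                                          risk_names()))
  )
}

#' Build counterfactual exposure trajectories under a scenario
#'
#' Applies each risk's rule to its projected series: a linear path in the
#' exposure metric from the baseline-year value to the rule's horizon
#' target (`(1 - r) x baseline` for relative reductions on the `value`
#' basis, `mid + (1 - r)(baseline - mid)` on the `excess` basis, the
#' baseline value for halts, the TMREL midpoint for `to_tmrel`). Years
#' before the baseline are unchanged. With `cap_at_projected = TRUE`
#' (default) the counterfactual never exceeds the projected path, so a
#' reduction target cannot raise exposure where the baseline trend already
#' beats it.
#'
#' @param projected Exposure data.frame (`year`, `sex`, `province`, `risk`,
#'   `metric`, `value`) covering baseline through horizon.
#' @param spec A [scenario_spec()].
#' @param cap_at_projected Logical; see above.
#' @return The data.frame with `value` replaced by the counterfactual.
#' @export
counterfactual_exposure <- function(projected, spec,
                                    cap_at_projected = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  b <- spec$baseline_year
  h <- spec$horizon_year
  if (!any(projected$year == b)) {
    stop("baseline year ", b, " missing from projected series")
  }
  sp <- risk_factor_specs()
  out <- projected
  pieces <- split(seq_len(nrow(projected)),
                  list(projected$risk, projected$sex, projected$province),
                  drop = TRUE)
  for (idx in pieces) {
    d <- projected[idx, ]
    risk <- d$risk[1]
    rule <- spec$rules[[risk]] %||% list(rule = "none")
    if (rule$rule == "none") next
    base_val <- d$value[match(b, d$year)]
    if (is.na(base_val)) {
      stop("baseline year ", b, " missing for risk ", risk)
    }
    i <- match(risk, sp$risk)
    mid <- (sp$tmrel_low[i] + sp$tmrel_high[i]) / 2
    target <- switch(rule$rule,
      relative_reduction = if (sp$reduction_basis[i] == "excess") {
        mid + (1 - rule$fraction) * (base_val - mid)
      } else {
        (1 - rule$fraction) * base_val
      },
      halt_at_baseline = base_val,
      to_tmrel = mid
    )
    frac <- pmin(pmax((d$year - b) / (h - b), 0), 1)
    cf <- base_val + frac * (target - base_val)
    cf[d$year < b] <- d$value[d$year < b]
    if (cap_at_projected) cf <- pmin(cf, d$value)
    if (d$metric[1] == "prevalence") cf <- pmin(pmax(cf, 0), 1)
    out$value[idx] <- cf
  }
  out
}

#' Per-cell potential impact fractions for a scenario
#'
#' For every admissible (risk, cause, sex, province, age band) cell at
#' `year`, compares the projected exposure with its counterfactual:
#' prevalence risks via [pif()], continuous-mean risks via
#' [pif_continuous()] with the risk's population standard deviation.
#'
#' @param projected,counterfactual Exposure data.frames (same dialect,
#'   same strata) containing `year`.
#' @param rr_table Relative-risk table (dialect of [generate_rr_table()]).
#' @param year Year at which to evaluate (typically the horizon).
#' @return A data.frame `risk`, `cause`, `sex`, `province`, `age_lo`,
#'   `age_hi`, `pif`.
#' @export
compute_pifs <- function(projected, counterfactual, rr_table, year) {
  sp <- risk_factor_specs()
  p_obs <- projected[projected$year == year, ]
  p_cf <- counterfactual[counterfactual$year == year, ]
  if (nrow(p_obs) == 0) stop("year ", year, " missing from projected series")
  key <- function(d) paste(d$risk, d$sex, d$province)
  cf_val <- p_cf$value[match(key(p_obs), key(p_cf))]
  out <- do.call(rbind, lapply(seq_len(nrow(rr_table)), function(i) {
    rr_row <- rr_table[i, ]
    sel <- which(p_obs$risk == rr_row$risk & p_obs$sex == rr_row$sex)
    if (length(sel) == 0) return(NULL)
    spi <- match(rr_row$risk, sp$risk)
    vals <- vapply(sel, function(j) {
      if (rr_row$kind == "categorical") {
        pif(p_obs$value[j], cf_val[j], rr_row$rr)
      } else {
        pif_continuous(p_obs$value[j], sp$pop_sd[spi], cf_val[j],
                       tmrel = c(sp$tmrel_low[spi], sp$tmrel_high[spi]),
                       rr_per_unit = rr_row$rr)
      }
    }, numeric(1))
    data.frame(risk = rr_row$risk, cause = rr_row$cause, sex = rr_row$sex,
               province = p_obs$province[sel], age_lo = rr_row$age_lo,
               age_hi = rr_row$age_hi, pif = vals,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Avoidable deaths under a scenario
#'
#' Multiplies per-cell potential impact fractions by projected deaths in
#' the same (sex, cause, province, age) cell. Per-risk rows use that risk's
#' PIF; the `"joint"` rows combine all risks acting on the cause with the
#' multiplicative joint formula `1 - prod(1 - PIF_i)`.
#'
#' @param projected_deaths Data.frame `sex`, `cause`, `province`, `age_lo`,
#'   `deaths` at the horizon year.
#' @param pifs Output of [compute_pifs()].
#' @return A data.frame `risk` (including `"joint"`), `cause`, `sex`,
#'   `province`, `age_lo`, `avoidable`.
#' @export
avoidable_deaths <- function(projected_deaths, pifs) {
  if (any(projected_deaths$deaths < 0)) stop("negative projected deaths")
  if (any(pifs$pif < 0 | pifs$pif > 1)) stop("PIFs must be in [0, 1]")
  dkey <- paste(projected_deaths$sex, projected_deaths$cause,
                projected_deaths$province, projected_deaths$age_lo)
  pifs$deaths <- projected_deaths$deaths[
    match(paste(pifs$sex, pifs$cause, pifs$province, pifs$age_lo), dkey)]
  pifs <- pifs[!is.na(pifs$deaths), ]
  per_risk <- pifs
  per_risk$avoidable <- per_risk$pif * per_risk$deaths
  jkey <- paste(pifs$sex, pifs$cause, pifs$province, pifs$age_lo)
  joint <- do.call(rbind, lapply(split(pifs, jkey), function(g) {
    data.frame(risk = "joint", cause = g$cause[1], sex = g$sex[1],
               province = g$province[1], age_lo = g$age_lo[1],
               pif = joint_paf(g$pif), deaths = g$deaths[1],
               stringsAsFactors = FALSE)
  }))
  joint$avoidable <- joint$pif * joint$deaths
  cols <- c("risk", "cause", "sex", "province", "age_lo", "pif",
            "avoidable")
  out <- rbind(per_risk[cols], joint[cols])
  rownames(out) <- NULL
  out
}

#' Recompute UPoD after subtracting avoidable deaths
#'
#' Subtracts a scenario's joint avoidable deaths from the projected deaths
#' cell by cell, rebuilds age-specific rates and recomputes the 30--70
#' indicator per stratum.
#'
#' @param projected_surface Mortality surface at the horizon year (`sex`,
#'   `cause`, `province`, `age_lo`, `deaths`, `population`).
#' @param avoidable Output of [avoidable_deaths()]; only rows with
#'   `risk == risk_label` are used.
#' @param by Stratification columns, as in [upod_from_surface()].
#' @param causes Causes included in the indicator.
#' @param risk_label Which avoidable-death rows to subtract (default
#'   `"joint"`).
#' @return A data.frame with the `by` columns and `upod`.
#' @export
adjusted_upod <- function(projected_surface, avoidable, by = "sex",
                          causes = ncd_causes(), risk_label = "joint") {
  av <- avoidable[avoidable$risk == risk_label, ]
  s <- projected_surface
  key <- paste(s$sex, s$cause, s$province, s$age_lo)
  akey <- paste(av$sex, av$cause, av$province, av$age_lo)
  sub <- av$avoidable[match(key, akey)]
  sub[is.na(sub)] <- 0
  if (any(sub > s$deaths + 1e-9)) {
    stop("avoidable deaths exceed projected deaths in some cell")
  }
  s$deaths <- pmax(s$deaths - sub, 0)
  upod_from_surface(s, causes = causes, by = by)
}

#' SDG 3.4 achievement flag
#'
#' Achieved if and only if the horizon value is at most two-thirds of the
#' baseline value (a one-third reduction), with the exact 2/3 factor and no
#' rounding.
#'
#' @param upod_baseline,upod_horizon Probabilities in \[0, 1\]; vectors
#'   recycle.
#' @return A data.frame `upod_baseline`, `upod_horizon`, `achieved`.
#' @examples
#' sdg_achievement(0.175, 0.108)$achieved  # TRUE
#' sdg_achievement(0.147, 0.108)$achieved  # FALSE
#' @export
sdg_achievement <- function(upod_baseline, upod_horizon) {
  if (any(upod_baseline < 0 | upod_baseline > 1) ||
      any(upod_horizon < 0 | upod_horizon > 1)) {
    stop("UPoD values must be in [0, 1]")
  }
  data.frame(upod_baseline = upod_baseline, upod_horizon = upod_horizon,
             achieved = upod_horizon <= (2 / 3) * upod_baseline)
}

#' Count achieving provinces
#'
#' Tabulates, per (sex, cause), how many provinces carry `achieved = TRUE`
#' — the tabular counterpart of the sub-national achievement maps.
#'
#' @param flags A data.frame with columns `sex`, `cause`, `province`,
#'   `achieved` (one row per province/sex/cause).
#' @return A data.frame `sex`, `cause`, `n_achieved`, `n_provinces`.
#' @export
subnational_summary <- function(flags) {
  grp <- interaction(flags$sex, flags$cause, drop = TRUE)
  out <- do.call(rbind, lapply(split(flags, grp), function(g) {
    data.frame(sex = g$sex[1], cause = g$cause[1],
               n_achieved = sum(g$achieved), n_provinces = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
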