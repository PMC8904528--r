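#' Age-specific mortality rate (5mx)
#'
#' @param deaths Death count(s), >= 0.
#' @param population Person-years at risk, > 0.
#' @param stratum Optional label(s) used in error messages.
#' @return `deaths / population`, the central death rate per person-year.
#' @examples
#' age_specific_rate(50, 10000)  # 0.005
#' @export
age_specific_rate <- function(deaths, population, stratum = NULL) {
  if (any(deaths < 0, na.rm = TRUE)) stop("deaths must be non-negative")
  bad <- which(!(population > 0))
  if (length(bad) > 0) {
    lab <- if (!is.null(stratum)) paste(stratum[bad], collapse = ", ")
           else paste("index", paste(bad, collapse = ", "))
    stop("non-positive population in stratum: ", lab)
  }
  deaths / population
}

#' Convert a death rate to a conditional death probability (5qx)
#'
#' Uses the standard abridged life-table conversion with deaths assumed to
#' occur on average at mid-interval (a_x = width/2), the convention of the
#' WHO premature-mortality indicator:
#' \deqn{{}_nq_x = \frac{n \, m_x}{1 + (n/2) \, m_x}}
#'
#' @param m Death rate(s) per person-year, >= 0.
#' @param width Interval width in years (default 5).
#' @return Probability of dying within the interval, in \[0, 1).
#' @export
prob_from_rate <- function(m, width = 5) {
  if (any(m < 0, na.rm = TRUE)) stop("rate m must be non-negative")
  if (width <= 0) stop("width must be positive")
  # the conversion exceeds 1 for extreme rates (m >= 2/width); a
  # probability is capped there (everyone in the band dies)
  pmin(width * m / (1 + (width / 2) * m), 1)
}

#' Unconditional probability of dying between ages 30 and 70 (40q30)
#'
#' The SDG 3.4 indicator: the probability that a 30-year-old dies before
#' exact age 70 from the causes whose rates are supplied, in the absence of
#' competition from other causes. Each of the eight 5-year age bands
#' \[30,35) ... \[65,70) contributes a conditional probability via
#' [prob_from_rate()], combined as
#' \deqn{{}_{40}q_{30} = 1 - \prod_x (1 - {}_5q_x).}
#' Cause-specific values use cause-specific rates in the same formula.
#'
#' @param rates Numeric vector of eight age-specific rates 5mx, ordered from
#'   the \[30,35) band upward. May be named by the lower age bound.
#' @param age_lo Expected lower bounds of the bands (default `seq(30, 65, 5)`).
#' @return A probability in \[0, 1\].
#' @examples
#' upod_30_70(rep(0.01, 8))
#' @export
upod_30_70 <- function(rates, age_lo = seq(30, 65, by = 5)) {
  if (!is.null(names(rates))) {
    have <- suppressWarnings(as.numeric(names(rates)))
    missing_bands <- setdiff(age_lo, have)
    if (length(missing_bands) > 0) {
      stop("missing age bands: ", paste(missing_bands, collapse = ", "))
    }
    rates <- rates[as.character(age_lo)]
  } else if (length(rates) != length(age_lo)) {
    stop("expected ", length(age_lo), " age bands, got ", length(rates),
         "; missing age bands: ",
         paste(age_lo[-seq_along(rates)], collapse = ", "))
  }
  if (anyNA(rates)) stop("rates contain NA")
  q <- prob_from_rate(rates, width = 5)
  1 - prod(1 - q)
}

#' Tabulate UPoD from a mortality surface
#'
#' Pools deaths and person-years across the requested strata (summing
#' numerators and denominators, never averaging ratios), computes age-band
#' rates restricted to ages 30--70 and applies [upod_30_70()].
#'
#' @param surface A mortality surface data.frame with columns `year`, `sex`,
#'   `province`, `cause`, `age_lo`, `age_hi`, `deaths`, `population` (the
#'   dialect written by [generate_registry()]).
#' @param causes Character vector of causes whose deaths are counted
#'   (default the four NCD categories).
#' @param by Stratification columns kept separate; any subset of
#'   `c("year", "sex", "province")`. Omitted dimensions are pooled
#'   (`sex` pooled = both sexes, `province` pooled = national).
#' @return A data.frame with the `by` columns and a `upod` column.
#' @export
upod_from_surface <- function(surface, causes = ncd_causes(),
                              by = "year") {
  stopifnot(all(by %in% c("year", "sex", "province")))
  keep <- surface$cause %in% causes & surface$age_lo >= 30 &
    surface$age_hi <= 70
  d <- surface[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for requested causes in ages 30-70")
  # deaths summed over causes; population must be counted once per
  # (year, sex, province, age) cell, not once per cause
  cell <- interaction(d$year, d$sex, d$province, d$age_lo, drop = TRUE)
  dd <- data.frame(
    year = tapply(d$year, cell, `[`, 1),
    sex = tapply(as.character(d$sex), cell, `[`, 1),
    province = tapply(d$province, cell, `[`, 1),
    age_lo = tapply(d$age_lo, cell, `[`, 1),
    deaths = as.numeric(tapply(d$deaths, cell, sum)),
    population = as.numeric(tapply(d$population, cell, `[`, 1))
  )
  grp <- if (length(by) > 0) {
    interaction(dd[by], drop = TRUE)
  } else {
    factor(rep(1, nrow(dd)))
  }
  out <- do.call(rbind, lapply(split(dd, grp), function(g) {
    agg_d <- tapply(g$deaths, g$age_lo, sum)
    agg_p <- tapply(g$population, g$age_lo, sum)
    m <- age_specific_rate(agg_d, agg_p,
                           stratum = paste0("age_lo=", names(agg_d)))
    res <- g[1, by, drop = FALSE]
    res$upod <- upod_30_70(m)
    res
  }))
  rownames(out) <- NULL
  if (length(by) > 0) out <- out[do.call(order, out[by]), , drop = FALSE]
  out
}

#' UPoD with parametric-bootstrap uncertainty
#'
#' Resamples death counts as Poisson around the observed counts, recomputes
#' the indicator per draw, and reports the 2.5th/97.5th percentiles as a 95%
#' uncertainty interval. The propagation method is this package's own
#' declaration; published indicator series report intervals without stating
#' one.
#'
#' @inheritParams upod_from_surface
#' @param draws Number of bootstrap draws (>= 100).
#' @param seed Integer seed; required for reproducibility.
#' @return A data.frame with the `by` columns plus `upod`, `ui_low`,
#'   `ui_high`.
#' @export
upod_uncertainty <- function(surface, causes = ncd_causes(), by = "year",
                             draws = 500, seed = 1) {
  if (draws < 100) stop("draws must be at least 100")
  point <- upod_from_surface(surface, causes = causes, by = by)
  sims <- with_seed(sub_seed(seed, "upod_uncertainty"), {
    vapply(seq_len(draws), function(i) {
      s <- surface
      s$deaths <- stats::rpois(nrow(s), s$deaths)
      upod_from_surface(s, causes = causes, by = by)$upod
    }, numeric(nrow(point)))
  })
  sims <- matrix(sims, nrow = nrow(point))
  point$ui_low <- apply(sims, 1, stats::quantile, probs = 0.025)
  point$ui_high <- apply(sims, 1, stats::quantile, probs = 0.975)
  point
}
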