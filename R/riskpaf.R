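#' Population attributable fraction for a categorical (prevalence) exposure
#'
#' Levin's formula with a single exposed category:
#' \deqn{PAF = \frac{p (RR - 1)}{p (RR - 1) + 1}}
#'
#' @param p Exposed prevalence in \[0, 1\].
#' @param rr Relative risk (> 0) of exposed vs unexposed.
#' @return Fraction in (-1, 1); non-negative whenever `rr >= 1`.
#' @examples
#' paf_categorical(0.5, 2)  # 1/3
#' @export
paf_categorical <- function(p, rr) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("prevalence p must be in [0, 1]")
  if (any(rr <= 0, na.rm = TRUE)) stop("rr must be positive")
  p * (rr - 1) / (p * (rr - 1) + 1)
}

#' Potential impact fraction for a categorical exposure
#'
#' Generalizes [paf_categorical()] to a counterfactual prevalence
#' `p_counterfactual`; equals the PAF when the counterfactual removes all
#' exposure and 0 when nothing changes:
#' \deqn{PIF = \frac{(p - p^*)(RR - 1)}{p (RR - 1) + 1}}
#'
#' @param p Observed prevalence in \[0, 1\].
#' @param p_counterfactual Counterfactual prevalence in \[0, 1\].
#' @param rr Relative risk (> 0).
#' @return Fraction; positive when exposure is reduced.
#' @export
pif <- function(p, p_counterfactual, rr) {
  if (any(p < 0 | p > 1, na.rm = TRUE) ||
      any(p_counterfactual < 0 | p_counterfactual > 1, na.rm = TRUE)) {
    stop("prevalences must be in [0, 1]")
  }
  if (any(rr <= 0, na.rm = TRUE)) stop("rr must be positive")
  (p * (rr - 1) - p_counterfactual * (rr - 1)) / (p * (rr - 1) + 1)
}

# Shared integration machinery for continuous exposures. RR(x) is log-linear
# above the TMREL midpoint and flat (RR = 1) below it:
#   RR(x) = rr_per_unit ^ max(0, x - tmrel_mid)
# The counterfactual distribution is either a point mass at the TMREL
# midpoint (mean RR exactly 1, the default) or uniform on the TMREL
# interval.
rr_curve_integral <- function(mean, sd, tmrel_mid_v, rr_per_unit,
                              grid_n = 2001) {
  lo <- mean - 6 * sd
  hi <- mean + 6 * sd
  x <- seq(lo, hi, length.out = grid_n)
  rrx <- rr_per_unit^pmax(0, x - tmrel_mid_v)
  if (any(!is.finite(rrx))) {
    stop("divergent integral: rr_per_unit too large for the grid")
  }
  fx <- stats::dnorm(x, mean, sd)
  w <- diff(x)
  vals <- rrx * fx
  sum((vals[-1] + vals[-length(vals)]) / 2 * w)
}

#' Population attributable fraction for a continuous exposure
#'
#' Compares the population exposure distribution `f = Normal(mean, sd)`
#' against the TMREL counterfactual distribution `f*` under a log-linear
#' excess-risk curve anchored at the TMREL midpoint:
#' \deqn{PAF = \frac{\int RR(x) f(x) dx - \int RR(x) f^*(x) dx}
#'                  {\int RR(x) f(x) dx}}
#' Integration is a trapezoid rule on a fixed grid over `mean +/- 6 sd`.
#'
#' @param mean,sd Mean and standard deviation of the population exposure
#'   distribution (`sd > 0`).
#' @param tmrel TMREL interval, numeric length 2 `c(low, high)`.
#' @param rr_per_unit Relative risk per unit of exposure above the TMREL
#'   midpoint (> 0).
#' @param grid_n Number of grid points (default 2001).
#' @param counterfactual `"midpoint"` (point mass at the TMREL midpoint;
#'   counterfactual mean RR is exactly 1) or `"uniform"` (uniform on the
#'   TMREL interval).
#' @return Fraction; 0 when the population sits at the TMREL midpoint or
#'   when `rr_per_unit = 1`.
#' @export
paf_continuous <- function(mean, sd, tmrel, rr_per_unit, grid_n = 2001,
                           counterfactual = c("midpoint", "uniform")) {
  counterfactual <- match.arg(counterfactual)
  if (sd <= 0) stop("sd must be positive")
  if (rr_per_unit <= 0) stop("rr_per_unit must be positive")
  mid <- sum(tmrel) / 2
  num_obs <- rr_curve_integral(mean, sd, mid, rr_per_unit, grid_n)
  num_cf <- if (counterfactual == "midpoint" || tmrel[1] == tmrel[2]) {
    1
  } else {
    x <- seq(tmrel[1], tmrel[2], length.out = grid_n)
    rrx <- rr_per_unit^pmax(0, x - mid)
    w <- diff(x)
    sum((rrx[-1] + rrx[-length(rrx)]) / 2 * w) / (tmrel[2] - tmrel[1])
  }
  (num_obs - num_cf) / num_obs
}

#' Potential impact fraction for a continuous exposure
#'
#' Shifts the exposure distribution from `Normal(mean, sd)` to
#' `Normal(mean_cf, sd_cf)` and measures the relative change in mean risk:
#' \deqn{PIF = \frac{\int RR(x) f(x) dx - \int RR(x) f_{cf}(x) dx}
#'                  {\int RR(x) f(x) dx}}
#'
#' @inheritParams paf_continuous
#' @param mean_cf,sd_cf Counterfactual distribution parameters
#'   (`sd_cf` defaults to `sd`).
#' @return Fraction; 0 when the counterfactual equals the observed
#'   distribution, and equal to [paf_continuous()] (midpoint convention)
#'   when the counterfactual collapses onto the TMREL midpoint.
#' @export
pif_continuous <- function(mean, sd, mean_cf, sd_cf = sd, tmrel,
                           rr_per_unit, grid_n = 2001) {
  if (sd <= 0 || sd_cf <= 0) stop("sd must be positive")
  if (rr_per_unit <= 0) stop("rr_per_unit must be positive")
  mid <- sum(tmrel) / 2
  num_obs <- rr_curve_integral(mean, sd, mid, rr_per_unit, grid_n)
  num_cf <- rr_curve_integral(mean_cf, sd_cf, mid, rr_per_unit, grid_n)
  (num_obs - num_cf) / num_obs
}

#' Joint population attributable fraction
#'
#' Multiplicative combination across risk factors:
#' \deqn{PAF_{joint} = 1 - \prod_{i=1}^{n} (1 - PAF_i)}
#' Order-invariant, bounded by `max(pafs)` below and `sum(pafs)` above, and
#' absorbing at 1.
#'
#' @param pafs Numeric vector of per-risk fractions, each in \[0, 1\].
#' @return The joint fraction in \[0, 1\].
#' @examples
#' joint_paf(c(0.5, 0.5))  # 0.75
#' @export
joint_paf <- function(pafs) {
  if (length(pafs) == 0) return(0)
  if (any(pafs < 0 | pafs > 1, na.rm = TRUE) || anyNA(pafs)) {
    stop("each PAF must be in [0, 1]")
  }
  1 - prod(1 - pafs)
}
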