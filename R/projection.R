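#' Enumerate the covariate-subset model space
#'
#' All subsets of `k` candidate covariates, including the empty
#' (intercept-only) model: `2^k` models, ordered lexicographically by
#' inclusion bitmask (covariate 1 is the least-significant bit).
#'
#' @param k Number of candidate covariates, 1--20. Larger spaces must use
#'   the `mc3` sampler instead of enumeration.
#' @return A logical matrix of dimension `2^k` x `k`; row i gives the
#'   inclusion pattern of model i - 1.
#' @examples
#' nrow(enumerate_models(10))  # 1024
#' @export
enumerate_models <- function(k) {
  if (k < 1) stop("k must be at least 1")
  if (k > 20) {
    stop("k > 20: enumeration infeasible, use sampler = 'mc3'")
  }
  ids <- 0:(2^k - 1)
  m <- matrix(FALSE, nrow = length(ids), ncol = k)
  for (j in seq_len(k)) {
    m[, j] <- bitwAnd(ids, bitwShiftL(1L, j - 1L)) > 0
  }
  m
}

#' Bayesian model averaging configuration
#'
#' @param covariate_labels Ordered covariate names (default the ten of
#'   [covariate_labels()]).
#' @param burn_in,iterations MC3 sampler settings (defaults 5000 and 20000).
#' @param sampler `"enumerate"` (exact, k <= 20) or `"mc3"` (Metropolis over
#'   model space).
#' @param seed Integer seed for the sampler and predictive draws.
#' @return A list of class `bma_config`.
#' @export
bma_config <- function(covariate_labels = ncdproj::covariate_labels(),
                       burn_in = 5000, iterations = 20000,
                       sampler = c("enumerate", "mc3"), seed = 1) {
  if (anyDuplicated(covariate_labels)) stop("covariate labels must be unique")
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  structure(list(covariate_labels = covariate_labels,
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 sampler = match.arg(sampler),
                 seed = as.integer(seed)),
            class = "bma_config")
}

# Log marginal likelihood of a linear model under Zellner's g-prior with
# g = n (unit information), flat priors on intercept and log sigma:
#   log ML = ((n - 1 - p)/2) log(1+g) - ((n - 1)/2) log(1 + g (1 - R^2))
# up to a model-independent constant. Empty model: 0.
log_marginal <- function(y, X, include, g) {
  n <- length(y)
  p <- sum(include)
  if (p == 0) {
    return(list(logml = 0, coef = numeric(0), rank_ok = TRUE,
                sigma2 = stats::var(y) * (n - 1) / n, xtxi = NULL))
  }
  Xc <- scale(X[, include, drop = FALSE], center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  qr_x <- qr(Xc)
  if (qr_x$rank < p) {
    return(list(logml = -Inf, coef = rep(0, p), rank_ok = FALSE,
                sigma2 = NA_real_, xtxi = NULL))
  }
  beta <- qr.coef(qr_x, yc)
  fitted <- Xc %*% beta
  tss <- sum(yc^2)
  rss <- sum((yc - fitted)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  r2 <- min(max(r2, 0), 1)
  logml <- ((n - 1 - p) / 2) * log(1 + g) -
    ((n - 1) / 2) * log(1 + g * (1 - r2))
  list(logml = logml, coef = beta, rank_ok = TRUE,
       sigma2 = rss / max(n - p - 1, 1),
       xtxi = chol2inv(qr.R(qr_x)))
}

#' Fit Bayesian model averaging over covariate subsets
#'
#' Linear regression of a (transformed) response on every subset of the
#' candidate covariates, weighted by marginal likelihood under a conjugate
#' unit-information (g = n) prior and a uniform prior over models. The
#' `mc3` sampler runs a Metropolis chain over the model space with the
#' configured burn-in and iteration counts and weights models by visit
#' frequency; enumeration is exact. Rank-deficient models receive weight 0
#' with a warning.
#'
#' @param y Numeric response (already transformed; see `transform` in
#'   [project_bma()] for the conventions used by the pipeline).
#' @param X Numeric covariate matrix, one column per candidate, same rows
#'   as `y`.
#' @param config A [bma_config()]; its `covariate_labels` must match
#'   `colnames(X)` when both are supplied.
#' @return An object of class `bma_fit`: `models` (logical inclusion
#'   matrix), `weights` (normalized), `pip` (posterior inclusion
#'   probability per covariate), and cached per-model statistics for
#'   prediction.
#' @export
fit_bma <- function(y, X, config = bma_config(covariate_labels = colnames(X))) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("y and X sizes differ")
  if (length(y) < 8) stop("need at least 8 observed time points")
  k <- ncol(X)
  g <- length(y)
  if (config$sampler == "enumerate") {
    models <- enumerate_models(k)
    stats_list <- lapply(seq_len(nrow(models)), function(i) {
      log_marginal(y, X, models[i, ], g)
    })
    logml <- vapply(stats_list, `[[`, numeric(1), "logml")
    if (any(!vapply(stats_list, `[[`, logical(1), "rank_ok"))) {
      warning("rank-deficient model(s) assigned weight 0")
    }
    w <- exp(logml - max(logml[is.finite(logml)]))
    w[!is.finite(w)] <- 0
    w <- w / sum(w)
  } else {
    res <- mc3_sample(y, X, g, config)
    models <- res$models
    stats_list <- res$stats
    w <- res$weights
  }
  pip <- as.numeric(crossprod(models, w))
  names(pip) <- colnames(X)
  structure(list(models = models, weights = w, pip = pip,
                 model_space_size = if (config$sampler == "enumerate") 2^k
                                    else NA_integer_,
                 stats = stats_list, y = y, X = X, g = g,
                 ybar = mean(y), xbar = colMeans(X), n = length(y),
                 config = config),
            class = "bma_fit")
}

# Metropolis over model space (MC3): single-bit flip proposals, acceptance
# by marginal-likelihood ratio (uniform model prior); weights are
# post-burn-in visit frequencies.
mc3_sample <- function(y, X, g, config) {
  k <- ncol(X)
  cache <- new.env(parent = emptyenv())
  get_stats <- function(inc) {
    key <- paste(as.integer(inc), collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <- log_marginal(y, X, inc, g)
    cache[[key]]
  }
  with_seed(sub_seed(config$seed, "mc3"), {
    inc <- rep(FALSE, k)
    cur <- get_stats(inc)
    visits <- new.env(parent = emptyenv())
    for (it in seq_len(config$iterations)) {
      j <- sample.int(k, 1)
      prop <- inc
      prop[j] <- !prop[j]
      cand <- get_stats(prop)
      if (is.finite(cand$logml) &&
          log(stats::runif(1)) < cand$logml - cur$logml) {
        inc <- prop
        cur <- cand
      }
      if (it > config$burn_in) {
        key <- paste(as.integer(inc), collapse = "")
        visits[[key]] <- (visits[[key]] %||% 0) + 1
      }
    }
    keys <- ls(visits)
    counts <- vapply(keys, function(kk) visits[[kk]], numeric(1))
    models <- do.call(rbind, lapply(keys, function(kk) {
      as.integer(strsplit(kk, "")[[1]]) > 0
    }))
    stats_list <- lapply(seq_len(nrow(models)),
                         function(i) get_stats(models[i, ]))
    list(models = models, weights = counts / sum(counts),
         stats = stats_list)
  })
}

#' Project a fitted BMA model over new covariate values
#'
#' The forecast is the weight-averaged per-model prediction using each
#' model's conditional maximum-likelihood coefficients (so a noiseless
#' linear truth extrapolates exactly); the 95% interval comes from draws of
#' the mixture predictive (model sampled by weight, then a normal
#' predictive draw), seeded and reproducible. Intervals widen as covariates
#' move away from the observed design.
#'
#' @param fit A `bma_fit`.
#' @param newX Matrix of covariate values (columns as in the fit) for the
#'   projection years.
#' @param draws Number of predictive draws for the interval (default 1000).
#' @param back_transform Function applied to mean and bounds before return
#'   (e.g. `inv_logit`); default identity.
#' @return A data.frame with `value`, `ui_low`, `ui_high` per row of `newX`.
#' @export
project_bma <- function(fit, newX, draws = 1000, back_transform = identity) {
  newX <- as.matrix(newX)
  if (ncol(newX) != ncol(fit$X)) stop("newX has wrong number of covariates")
  if (anyNA(newX)) stop("missing covariate values in projection input")
  nm <- nrow(fit$models)
  # per-model mean and predictive sd for each new row
  mu <- matrix(0, nrow(newX), nm)
  sdv <- matrix(0, nrow(newX), nm)
  for (i in seq_len(nm)) {
    st <- fit$stats[[i]]
    inc <- fit$models[i, ]
    xc <- sweep(newX[, inc, drop = FALSE], 2, fit$xbar[inc])
    if (sum(inc) == 0) {
      mu[, i] <- fit$ybar
      quad <- 0
    } else if (!st$rank_ok) {
      mu[, i] <- fit$ybar
      quad <- 0
    } else {
      mu[, i] <- fit$ybar + as.numeric(xc %*% st$coef)
      quad <- rowSums((xc %*% st$xtxi) * xc)
    }
    s2 <- if (is.na(st$sigma2)) 0 else st$sigma2
    sdv[, i] <- sqrt(s2 * (1 + 1 / fit$n + quad))
  }
  mean_pred <- as.numeric(mu %*% fit$weights)
  qs <- with_seed(sub_seed(fit$config$seed, "project_bma"), {
    t(vapply(seq_len(nrow(newX)), function(r) {
      mi <- sample.int(nm, draws, replace = TRUE, prob = fit$weights)
      dr <- stats::rnorm(draws, mu[r, mi], sdv[r, mi])
      stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    }, numeric(2)))
  })
  data.frame(value = back_transform(mean_pred),
             ui_low = back_transform(qs[, 1]),
             ui_high = back_transform(qs[, 2]))
}

#' Spatiotemporal interpolation of sparse exposure series
#'
#' Fills every year of `years` for each (risk, sex, province) series from
#' sparse survey rounds: a national linear trend is fit to all provinces'
#' observations, each province receives a mean-residual offset shrunk toward
#' zero with weight `n_p / (n_p + tau)`, and observed province-years are
#' reproduced exactly. Years outside the observed rounds are back-cast or
#' projected with the same linear trend (provenance `"projected"`).
#' Prevalence-type values are clamped to \[0, 1\].
#'
#' @param series An exposure data.frame (`year`, `sex`, `province`, `risk`,
#'   `metric`, `value`, dialect of [generate_surveys()]).
#' @param years Integer years to fill (e.g. `2001:2030`).
#' @param tau Shrinkage constant (default 4, in units of observation
#'   counts).
#' @return A data.frame with columns `year`, `sex`, `province`, `risk`,
#'   `metric`, `value`, `provenance`.
#' @export
spatiotemporal_interpolate <- function(series, years, tau = 4) {
  pieces <- split(series, list(series$risk, series$sex), drop = TRUE)
  out <- lapply(pieces, function(d) {
    obs_years <- sort(unique(d$year))
    if (length(obs_years) < 2) {
      stop("cannot interpolate risk '", d$risk[1], "' (", d$sex[1],
           "): only one observed round")
    }
    fit <- stats::lm(value ~ year, data = d)
    a <- stats::coef(fit)[1]
    b <- stats::coef(fit)[2]
    resid <- d$value - (a + b * d$year)
    provs <- sort(unique(d$province))
    off <- vapply(provs, function(p) {
      r <- resid[d$province == p]
      mean(r) * length(r) / (length(r) + tau)
    }, numeric(1))
    grid <- expand.grid(year = years, province = provs,
                        KEEP.OUT.ATTRS = FALSE)
    grid$value <- a + b * grid$year + off[match(grid$province, provs)]
    grid$provenance <- ifelse(grid$year > max(obs_years) |
                                grid$year < min(obs_years),
                              "projected", "interpolated")
    key_obs <- paste(d$year, d$province)
    hit <- match(paste(grid$year, grid$province), key_obs)
    grid$value[!is.na(hit)] <- d$value[hit[!is.na(hit)]]
    grid$provenance[!is.na(hit)] <- "observed"
    if (d$metric[1] == "prevalence") {
      grid$value <- pmin(pmax(grid$value, 0), 1)
    }
    data.frame(year = grid$year, sex = d$sex[1], province = grid$province,
               risk = d$risk[1], metric = d$metric[1], value = grid$value,
               provenance = grid$provenance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gaussian-process smoothing of a yearly series
#'
#' GP regression with a squared-exponential kernel
#' `k(t, t') = amplitude^2 exp(-(t - t')^2 / (2 length_scale^2))`, fixed
#' hyperparameters and prior mean equal to the data mean. Returns the
#' posterior mean and a 95% band at `x_out`; far from data the posterior
#' reverts to the prior mean.
#'
#' @param x,y Observed locations and values (>= 3 points).
#' @param x_out Locations at which to evaluate (default `x`).
#' @param amplitude Kernel amplitude (> 0).
#' @param length_scale Kernel length scale in years (> 0).
#' @param noise_sd Observation noise standard deviation (>= 0; 0 gives an
#'   interpolating smoother up to jitter).
#' @return A data.frame `x`, `value`, `ui_low`, `ui_high`.
#' @export
gpr_smooth <- function(x, y, x_out = x, amplitude = stats::sd(y),
                       length_scale = 10, noise_sd = 0.1) {
  if (length(x) < 3) stop("need at least 3 points")
  if (!is.finite(amplitude) || amplitude <= 0 || length_scale <= 0) {
    stop("amplitude and length_scale must be positive")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  m0 <- mean(y)
  k_fun <- function(a, b) {
    amplitude^2 * exp(-outer(a, b, `-`)^2 / (2 * length_scale^2))
  }
  K <- k_fun(x, x) + diag(noise_sd^2 + 1e-10 * amplitude^2, length(x))
  Ks <- k_fun(x_out, x)
  alpha <- solve(K, y - m0)
  mean_post <- m0 + as.numeric(Ks %*% alpha)
  v <- amplitude^2 - rowSums((Ks %*% solve(K)) * Ks)
  v <- pmax(v, 0)
  data.frame(x = x_out, value = mean_post,
             ui_low = mean_post - 1.96 * sqrt(v),
             ui_high = mean_post + 1.96 * sqrt(v))
}

#' Natural-spline extrapolation of covariate series
#'
#' Fits a natural cubic spline through each (province, covariate) series
#' and evaluates it on all years up to the horizon; beyond the data range
#' the natural spline continues linearly with the boundary slope.
#' Urbanization is clamped to \[0, 100\].
#'
#' @param covariates A covariate data.frame (`year`, `province`,
#'   `covariate`, `value`, dialect of [generate_covariates()]).
#' @param horizon_year Last year to produce.
#' @return A data.frame in the same dialect plus a `provenance` column.
#' @export
spline_extrapolate <- function(covariates, horizon_year) {
  pieces <- split(covariates, list(covariates$covariate,
                                   covariates$province), drop = TRUE)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$year), ]
    if (nrow(d) < 4) {
      stop("covariate '", d$covariate[1], "' province ", d$province[1],
           ": need at least 4 observed points")
    }
    yrs <- seq(min(d$year), horizon_year)
    f <- stats::splinefun(d$year, d$value, method = "natural")
    v <- f(yrs)
    if (d$covariate[1] == "urbanization") v <- pmin(pmax(v, 0), 100)
    if (d$covariate[1] == "wealth_index") v <- pmin(pmax(v, 0), 1)
    data.frame(year = yrs, province = d$province[1],
               covariate = d$covariate[1], value = v,
               provenance = ifelse(yrs %in% d$year, "observed", "projected"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Project mortality rates to the horizon year
#'
#' Per (sex, cause, age band, province) stratum, fits a log-linear time
#' trend to death counts with a Poisson likelihood and a person-years
#' offset, shrinks the province slope toward the national (pooled) slope
#' with weight `D / (D + tau)` (D = total deaths in the stratum), and
#' extrapolates. All-zero strata project a zero rate with a warning.
#'
#' @param surface A mortality surface (dialect of [generate_registry()]).
#' @param years Years at which to return projected rates (default: observed
#'   years through `horizon_year`).
#' @param horizon_year Projection horizon.
#' @param tau Shrinkage constant in death counts (default 50).
#' @return A data.frame `year`, `sex`, `province`, `cause`, `age_lo`,
#'   `age_hi`, `rate`, `provenance`.
#' @export
project_mortality <- function(surface, horizon_year, years = NULL,
                              tau = 50) {
  if (is.null(years)) years <- seq(min(surface$year), horizon_year)
  y0 <- min(surface$year)
  n_obs_years <- length(unique(surface$year))
  if (n_obs_years < 8) stop("need at least 8 observed years")
  fit_trend <- function(deaths, pop, yr) {
    # Poisson log-linear fit: log E[deaths] = a + b (yr - y0) + log(pop)
    if (sum(deaths) <= 0) return(c(NA_real_, NA_real_))
    f <- suppressWarnings(
      stats::glm(deaths ~ I(yr - y0), offset = log(pop),
                 family = stats::poisson())
    )
    stats::coef(f)
  }
  nat_key <- interaction(surface$sex, surface$cause, surface$age_lo,
                         drop = TRUE)
  nat_coef <- lapply(split(surface, nat_key), function(d) {
    agg_d <- tapply(d$deaths, d$year, sum)
    agg_p <- tapply(d$population, d$year, sum)
    fit_trend(as.numeric(agg_d), as.numeric(agg_p),
              as.numeric(names(agg_d)))
  })
  any_zero <- FALSE
  prov_key <- interaction(surface$sex, surface$cause, surface$age_lo,
                          surface$province, drop = TRUE)
  out <- lapply(split(surface, prov_key), function(d) {
    nk <- paste(d$sex[1], d$cause[1], d$age_lo[1], sep = ".")
    nat <- nat_coef[[nk]]
    D <- sum(d$deaths)
    res <- data.frame(
      year = years, sex = d$sex[1], province = d$province[1],
      cause = d$cause[1], age_lo = d$age_lo[1], age_hi = d$age_hi[1],
      stringsAsFactors = FALSE
    )
    if (D <= 0) {
      any_zero <<- TRUE
      res$rate <- 0
    } else {
      co <- fit_trend(d$deaths, d$population, d$year)
      w <- D / (D + tau)
      b_nat <- if (!is.na(nat[2])) nat[2] else co[2]
      b <- w * co[2] + (1 - w) * b_nat
      tbar <- mean(d$year - y0)
      a <- (co[1] + co[2] * tbar) - b * tbar
      res$rate <- exp(a + b * (years - y0))
    }
    res$provenance <- ifelse(years %in% d$year, "observed", "projected")
    res
  })
  if (any_zero) warning("all-zero stratum projected as zero rate")
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
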