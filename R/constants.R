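#' Canonical cause and risk-factor labels
#'
#' The four major NCD categories tracked by the SDG 3.4 indicator, the full
#' generator cause set (the four categories plus a residual `"other"`), and
#' the six modifiable risk factors of the WHO global monitoring framework.
#'
#' @return Character vectors of labels.
#' @export
ncd_causes <- function() {
  c("cancers", "CVDs", "asthma_COPD", "diabetes_mellitus")
}

#' @rdname ncd_causes
#' @export
all_causes <- function() {
  c(ncd_causes(), "other")
}

#' @rdname ncd_causes
#' @export
risk_names <- function() {
  c("diabetes", "hypertension", "obesity", "inactivity", "smoking", "salt")
}

#' Risk-factor specifications
#'
#' One row per risk factor: how exposure is measured (`prevalence` in
#' \[0,1\] or a `continuous` population mean), its units, the theoretical
#' minimum risk exposure level (TMREL) as an interval, the cross-sectional
#' population standard deviation used for continuous exposure distributions,
#' and the basis on which a relative-reduction scenario rule acts
#' (`"value"`: the exposure metric itself; `"excess"`: the excess of the mean
#' over the TMREL midpoint, a prevalence-of-raised-exposure style reduction
#' expressed on the mean).
#'
#' TMRELs: blood pressure 110--115 mmHg, body-mass index 21--25 kg/m^2,
#' salt (24h urinary sodium equivalent) 1--5 g/day; the prevalence-type
#' risks (diabetes, physical inactivity, current smoking) have a degenerate
#' TMREL at zero prevalence.
#'
#' @return A data.frame with columns `risk`, `exposure_kind`, `units`,
#'   `tmrel_low`, `tmrel_high`, `pop_sd`, `reduction_basis`.
#' @export
risk_factor_specs <- function() {
  data.frame(
    risk = risk_names(),
    exposure_kind = c("prevalence", "continuous", "continuous",
                      "prevalence", "prevalence", "continuous"),
    units = c("proportion", "mmHg", "kg/m2", "proportion", "proportion",
              "g/day"),
    tmrel_low = c(0, 110, 21, 0, 0, 1),
    tmrel_high = c(0, 115, 25, 0, 0, 5),
    pop_sd = c(NA, 15, 4.5, NA, NA, 3),
    reduction_basis = c("value", "excess", "value", "value", "value",
                        "value"),
    stringsAsFactors = FALSE
  )
}

#' TMREL midpoint for a risk factor
#' @param risk Risk-factor name.
#' @return Numeric midpoint of the TMREL interval.
#' @export
tmrel_mid <- function(risk) {
  sp <- risk_factor_specs()
  i <- match(risk, sp$risk)
  if (anyNA(i)) stop("unknown risk factor: ", paste(risk[is.na(i)], collapse = ", "))
  (sp$tmrel_low[i] + sp$tmrel_high[i]) / 2
}

#' Admissible risk--cause pairs
#'
#' The risk-to-disease mapping collapsed to the four NCD categories.
#' Salt's indirect cardiovascular/respiratory pathways are treated as direct
#' pairs; salt's direct stomach-cancer effect maps to the `cancers` category.
#' Pairs outside this table (for example salt with diabetes mellitus) are
#' rejected by the relative-risk generators and input validators.
#'
#' @return A data.frame with columns `risk` and `cause`.
#' @export
risk_cause_pairs <- function() {
  pairs <- list(
    diabetes = c("diabetes_mellitus", "CVDs"),
    hypertension = c("CVDs", "asthma_COPD"),
    obesity = c("cancers", "CVDs", "diabetes_mellitus"),
    inactivity = c("cancers", "CVDs", "diabetes_mellitus"),
    smoking = c("cancers", "CVDs", "asthma_COPD", "diabetes_mellitus"),
    salt = c("cancers", "CVDs", "asthma_COPD")
  )
  data.frame(
    risk = rep(names(pairs), lengths(pairs)),
    cause = unlist(pairs, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Covariate labels available to the projection stage
#'
#' The ten candidate covariates: the six risk-factor exposures plus wealth
#' index, years of schooling, urbanization percentage and population.
#'
#' @return Character vector of length 10.
#' @export
covariate_labels <- function() {
  c(risk_names(), "wealth_index", "years_schooling", "urbanization",
    "population")
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is untouched. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed (stable, < 2^31) from a master seed and a stream label.
sub_seed <- function(seed, stream) {
  h <- fnv1a(paste0(stream, ":", format(seed, scientific = FALSE)))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash of a character scalar (dependency-free; used for seed
# streams and config fingerprints in output metadata, not for security).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte, then 32-bit multiply split to stay inside
    # double precision
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
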