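# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths.

# Small world: 3 provinces, full year range, noise on by default.
tiny_config <- function(seed = 42, ...) {
  sim_config(n_provinces = 3, seed = seed, ...)
}

# Discrete per-cohort survival simulation: start n individuals at 30,
# kill band by band with the given conditional probabilities, return the
# fraction dead by 70. Independent of upod_30_70's product formula.
microsim_upod <- function(q, n = 1e6) {
  alive <- n
  dead <- 0
  for (qi in q) {
    d <- stats::rbinom(1, alive, qi)
    dead <- dead + d
    alive <- alive - d
  }
  dead / n
}

# Loop-free product oracle for the joint PAF.
product_oracle <- function(pafs) {
  1 - exp(sum(log(1 - pafs)))
}

# Monte-Carlo oracle for the continuous PAF with the midpoint
# counterfactual: mean relative risk under the exposure distribution.
mc_paf_continuous <- function(mean, sd, tmrel_mid, rr_per_unit, n = 1e6) {
  x <- stats::rnorm(n, mean, sd)
  rrx <- rr_per_unit^pmax(0, x - tmrel_mid)
  (mean(rrx) - 1) / mean(rrx)
}

# Closed-form temporary life expectancy oracle via explicit survivorship
# products (independent of build_life_table's recursion).
closed_form_e30_70 <- function(m, width = 5) {
  q <- width * m / (1 + (width / 2) * m)
  l <- cumprod(c(1, 1 - q))
  sum(width * l[seq_along(q)] - (width / 2) * l[seq_along(q)] * q)
}
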