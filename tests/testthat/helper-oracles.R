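# Independent oracles and small fixtures shared across tests.

# JZS paired Bayes factor via its other definition: marginal likelihood of t
# under a Cauchy(0, r) prior on effect size (noncentral-t mixture), against
# the central-t null. Independent of the g-integral used by the package.
oracle_bf10_nct <- function(t_stat, n, r_scale = sqrt(2) / 2) {
  nu <- n - 1
  num <- integrate(function(d)
    suppressWarnings(dt(t_stat, nu, ncp = sqrt(n) * d)) * dcauchy(d, 0, r_scale),
    -Inf, Inf, rel.tol = 1e-10)$value
  num / dt(t_stat, nu)
}

# Brute-force grid minimiser of the psychometric negative log-likelihood.
oracle_grid_nll <- function(contrast, response, mu_range, sigma_range,
                            step = 0.05, gamma = 0.02, lambda = 0.02) {
  mus <- seq(mu_range[1], mu_range[2], by = step)
  sigmas <- seq(sigma_range[1], sigma_range[2], by = step)
  y <- as.numeric(response)
  best <- Inf
  for (s in sigmas) {
    psi <- gamma + (1 - gamma - lambda) *
      pnorm(outer(contrast, mus, `-`) / s)   # n_trials x n_mus
    psi <- pmin(pmax(psi, 1e-9), 1 - 1e-9)
    nll <- -colSums(y * log(psi) + (1 - y) * log(1 - psi))
    best <- min(best, min(nll))
  }
  best
}

# Deterministic threshold responder: "lighter" iff contrast exceeds mu.
run_threshold_staircase <- function(mu, cfg = staircase_config(),
                                    start_level = 0) {
  st <- with_preserved_seed(1L, init_staircase("homog_black.black.b1", cfg))
  st$level <- start_level
  n <- 0
  while (!st$finished) {
    st <- staircase_update(st, st$level > mu)
    n <- n + 1
    if (n > 1000) stop("threshold staircase failed to terminate")
  }
  st
}

# Simulate one staircase against a cumulative Gaussian observer (no lapses).
run_gaussian_staircase <- function(mu, sigma, cfg = staircase_config()) {
  st <- init_staircase("homog_black.black.b1", cfg)
  while (!st$finished)
    st <- staircase_update(st, runif(1) < pnorm((st$level - mu) / sigma))
  st
}

# Small two-observer configuration for fast pipeline tests.
tiny_config <- function(seed = 1L, ...) {
  run_config(seed = seed, population = population_config(n_observers = 2, ...))
}
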