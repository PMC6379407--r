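# Evaluate expr under a fixed seed without clobbering the caller's RNG stream.
#' Run an expression under a temporary RNG seed
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generative parameters of one simulated observer
#'
#' The observer reports whether the matching triangle looks lighter than the
#' attended illusory triangle. Their probability of a "lighter" report follows
#' a cumulative Gaussian in matching-triangle Weber contrast, with a
#' condition-specific point of subjective equality (PSE) and a spread shared
#' across cue polarity. On mixed displays two illusory surfaces compete;
#' `compliance` is the probability of evaluating the cued one, and a lapse
#' selects the competing surface (or guesses, if `noncompliance_mode` is
#' `"guess"`).
#'
#' @param observer_id identifier
#' @param pse named numeric vector of true PSEs (Weber %), one per
#'   `condition_id` of [condition_grid()]
#' @param slope_sigma psychometric spread (Weber %), shared across conditions
#' @param guess_gamma,lapse_lambda lower/upper asymptote rates, each in
#'   \[0, 0.1\]
#' @param compliance probability of attending the cued triangle on a mixed
#'   trial, in \[0.5, 1\]
#' @param noncompliance_mode `"opposite"` (mis-selection of the competing
#'   surface) or `"guess"` (stimulus-independent coin flip)
#' @return object of class `observer_params`
#' @export
observer_params <- function(observer_id, pse, slope_sigma,
                            guess_gamma = 0.02, lapse_lambda = 0.02,
                            compliance = 0.95,
                            noncompliance_mode = c("opposite", "guess")) {
  noncompliance_mode <- match.arg(noncompliance_mode)
  ids <- condition_grid()$condition_id
  if (!all(ids %in% names(pse)))
    stop("pse must be named with all 20 condition ids; missing: ",
         paste(setdiff(ids, names(pse)), collapse = ", "))
  if (slope_sigma <= 0) stop("slope_sigma must be positive")
  if (guess_gamma < 0 || guess_gamma > 0.1 || lapse_lambda < 0 || lapse_lambda > 0.1)
    stop("asymptote rates must lie in [0, 0.1]")
  if (guess_gamma + lapse_lambda >= 1) stop("gamma + lambda must be < 1")
  if (compliance < 0.5 || compliance > 1) stop("compliance must lie in [0.5, 1]")
  structure(list(observer_id = observer_id, pse = pse[ids],
                 slope_sigma = slope_sigma, guess_gamma = guess_gamma,
                 lapse_lambda = lapse_lambda, compliance = compliance,
                 noncompliance_mode = noncompliance_mode),
            class = "observer_params")
}

#' Probability of a "lighter" report
#'
#' Psi(c) = gamma + (1 - gamma - lambda) * Phi((c - mu) / sigma), where c is
#' the matching triangle's Weber contrast and mu the condition's PSE. On mixed
#' displays the returned value is the compliance-weighted mixture over the
#' cued and competing surface (or over a 0.5 guess in `"guess"` mode);
#' homogeneous displays have a single surface and compliance plays no role.
#'
#' @param params an [observer_params()]
#' @param cond_id a `condition_id` from [condition_grid()]
#' @param contrast matching-triangle Weber contrast (%), vectorised
#' @return probability (vector) of reporting "lighter"
#' @export
response_probability <- function(params, cond_id, contrast) {
  stopifnot(inherits(params, "observer_params"))
  if (!cond_id %in% names(params$pse)) stop("unknown condition id: ", cond_id)
  psi <- function(mu) params$guess_gamma +
    (1 - params$guess_gamma - params$lapse_lambda) *
    stats::pnorm((contrast - mu) / params$slope_sigma)
  p <- psi(params$pse[[cond_id]])
  opp <- opposite_condition_id(cond_id)
  if (opp != cond_id && params$compliance < 1) {
    alt <- if (params$noncompliance_mode == "opposite") psi(params$pse[[opp]]) else 0.5
    p <- params$compliance * p + (1 - params$compliance) * alt
  }
  p
}

#' Draw one binary response
#'
#' Bernoulli draw at [response_probability()], consuming one uniform deviate
#' from the current RNG stream; bit-reproducible under a fixed seed.
#'
#' @inheritParams response_probability
#' @return logical: `TRUE` if the matching triangle is reported lighter
#' @export
simulate_response <- function(params, cond_id, contrast) {
  stats::runif(1) < response_probability(params, cond_id, contrast)
}

#' Population-level generative configuration
#'
#' Group-mean PSEs default to the qualitative effect structure of the
#' experiment: attending black makes the illusory surface look lighter
#' (positive PSE) and attending white darker, the homogeneous effect exceeds
#' the mixed effect, the mixed-display effect reverses sign at the most
#' extreme blur, and the homogeneous polarity difference collapses there
#' (with an overall "lighter" bias). The default magnitudes are
#' order-of-magnitude placeholders, not measured values.
#'
#' @param n_observers number of simulated participants
#' @param group_pse named numeric vector of group-mean PSEs (Weber %) per
#'   condition id; defaults to [default_group_pse()]
#' @param between_sd observer-level PSE jitter sd (Weber %)
#' @param slope_mean,slope_sd mean and sd of observer psychometric spreads
#'   (Weber %); slopes are drawn from a normal truncated below at 0.5
#' @param guess_gamma,lapse_lambda,compliance,noncompliance_mode passed to
#'   each [observer_params()]
#' @return object of class `population_config`
#' @export
population_config <- function(n_observers = 15, group_pse = default_group_pse(),
                              between_sd = 2, slope_mean = 3, slope_sd = 1,
                              guess_gamma = 0.02, lapse_lambda = 0.02,
                              compliance = 0.95,
                              noncompliance_mode = "opposite") {
  if (n_observers < 2) stop("n_observers must be >= 2")
  ids <- condition_grid()$condition_id
  if (!all(ids %in% names(group_pse)))
    stop("group_pse must cover all 20 condition ids")
  cfg <- structure(list(n_observers = as.integer(n_observers),
                        group_pse = group_pse[ids], between_sd = between_sd,
                        slope_mean = slope_mean, slope_sd = slope_sd,
                        guess_gamma = guess_gamma, lapse_lambda = lapse_lambda,
                        compliance = compliance,
                        noncompliance_mode = noncompliance_mode),
                   class = "population_config")
  viol <- check_sign_structure(group_pse)
  if (length(viol))
    warning("group_pse deviates from the canonical effect structure: ",
            paste(viol, collapse = "; "))
  cfg
}

#' Default group-mean PSEs (Weber %)
#'
#' Placeholder effect sizes encoding only the sign/ordering structure:
#' homogeneous +/-4 at blur levels 1-4, mixed +/-2 at blur levels 1-4 with the
#' sign reversed at blur level 5, and homogeneous blur level 5 at +3 for both
#' polarities (a shared lighter-bias with near-zero polarity difference).
#'
#' @return named numeric vector over the 20 condition ids
#' @export
default_group_pse <- function() {
  grid <- condition_grid()
  val <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    black <- grid$cued_polarity[i] == "black"
    mixed <- grid$inducer_condition[i] == "mixed"
    extreme <- grid$blur_level[i] == 5
    val[i] <- if (!mixed) {
      if (extreme) 3 else if (black) 4 else -4
    } else {
      if (extreme) { if (black) -2 else 2 } else { if (black) 2 else -2 }
    }
  }
  stats::setNames(val, grid$condition_id)
}

# returns character vector of violated sign/ordering constraints (empty = ok)
check_sign_structure <- function(group_pse) {
  grid <- condition_grid()
  gp <- function(ind, pol, b) group_pse[[condition_id(ind, pol, b)]]
  viol <- character(0)
  for (b in 1:4) {
    if (gp("homog_black", "black", b) <= gp("homog_white", "white", b))
      viol <- c(viol, sprintf("homogeneous black <= white at blur %d", b))
    if (gp("mixed", "black", b) <= gp("mixed", "white", b))
      viol <- c(viol, sprintf("mixed black-cued <= white-cued at blur %d", b))
  }
  if (gp("mixed", "black", 5) >= gp("mixed", "white", 5))
    viol <- c(viol, "no sign reversal at blur 5 in the mixed condition")
  if (abs(gp("homog_black", "black", 5) - gp("homog_white", "white", 5)) > 1)
    viol <- c(viol, "homogeneous polarity difference at blur 5 not near zero")
  viol
}

#' Draw a population of simulated observers
#'
#' Per-observer PSEs are the group means plus independent Normal(0,
#' `between_sd`) jitter per condition; spreads are drawn from a normal
#' truncated below at 0.5 Weber % so every psychometric function is proper.
#'
#' @param cfg a [population_config()]
#' @param seed integer seed
#' @return list of [observer_params()], length `cfg$n_observers`
#' @export
make_population <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "population_config"))
  ids <- names(cfg$group_pse)
  with_preserved_seed(seed, {
    lapply(seq_len(cfg$n_observers), function(i) {
      pse <- cfg$group_pse + stats::rnorm(length(ids), 0, cfg$between_sd)
      slope <- 0
      while (slope < 0.5) slope <- stats::rnorm(1, cfg$slope_mean, cfg$slope_sd)
      observer_params(observer_id = sprintf("obs%02d", i),
                      pse = stats::setNames(pse, ids), slope_sigma = slope,
                      guess_gamma = cfg$guess_gamma,
                      lapse_lambda = cfg$lapse_lambda,
                      compliance = cfg$compliance,
                      noncompliance_mode = cfg$noncompliance_mode)
    })
  })
}

#' Export observer parameters to a data frame (audit table)
#'
#' @param population list of [observer_params()]
#' @return data frame with one row per observer x condition
#' @export
population_to_df <- function(population) {
  grid <- condition_grid()
  do.call(rbind, lapply(population, function(ob) {
    data.frame(observer_id = ob$observer_id, grid[, 1:5],
               true_pse = as.numeric(ob$pse[grid$condition_id]),
               slope_sigma = ob$slope_sigma, guess_gamma = ob$guess_gamma,
               lapse_lambda = ob$lapse_lambda, compliance = ob$compliance,
               row.names = NULL)
  }))
}
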