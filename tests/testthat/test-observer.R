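make_observer <- function(...) {
  ids <- condition_grid()$condition_id
  defaults <- list(observer_id = "obs01",
                   pse = setNames(rep(0, 20), ids), slope_sigma = 3)
  do.call(observer_params, utils::modifyList(defaults, list(...)))
}

test_that("the psychometric generative model matches its closed form", {
  ids <- condition_grid()$condition_id
  pse <- setNames(rep(0, 20), ids)
  pse["homog_black.black.b2"] <- 4
  ob <- make_observer(pse = pse, guess_gamma = 0.03, lapse_lambda = 0.03,
                      compliance = 1)
  # at the PSE with equal asymptotes the curve crosses one half
  expect_equal(response_probability(ob, "homog_black.black.b2", 4), 0.5)
  # upper asymptote is 1 - lambda
  expect_equal(response_probability(ob, "homog_black.black.b2", 1e6), 1 - 0.03)
  ob0 <- make_observer(pse = pse, guess_gamma = 0, lapse_lambda = 0)
  expect_equal(response_probability(ob0, "homog_black.black.b2", 7),
               pnorm(1), tolerance = 1e-12)  # Phi(1) ~ 0.8413
  # monotone non-decreasing in contrast for every condition
  cs <- seq(-30, 30, by = 0.5)
  ob2 <- make_observer(pse = setNames(rnorm(20, 0, 3), ids),
                       compliance = 0.8, guess_gamma = 0.05,
                       lapse_lambda = 0.02)
  for (id in ids[c(1, 6, 11, 16)])
    expect_true(all(diff(response_probability(ob2, id, cs)) >= 0))
  expect_error(response_probability(ob, "no_such_condition", 0), "unknown")
})

test_that("attentional non-compliance pulls mixed-condition PSEs together", {
  ids <- condition_grid()$condition_id
  pse <- setNames(rep(0, 20), ids)
  pse["mixed.black.b2"] <- 3
  pse["mixed.white.b2"] <- -3
  effective_pse <- function(compliance, mode = "opposite") {
    ob <- make_observer(pse = pse, guess_gamma = 0, lapse_lambda = 0,
                        compliance = compliance, noncompliance_mode = mode)
    uniroot(function(c) response_probability(ob, "mixed.black.b2", c) - 0.5,
            c(-10, 10), tol = 1e-9)$root
  }
  expect_equal(effective_pse(1), 3, tolerance = 1e-6)
  expect_lt(effective_pse(0.8), effective_pse(1))
  expect_lt(effective_pse(0.6), effective_pse(0.8))
  expect_gt(effective_pse(0.6), 0)
  # symmetric guess-mode lapses leave the PSE put but flatten the curve
  expect_equal(effective_pse(0.8, "guess"), 3, tolerance = 1e-6)
  ob_g <- make_observer(pse = pse, guess_gamma = 0, lapse_lambda = 0,
                        compliance = 0.8, noncompliance_mode = "guess")
  ob_f <- make_observer(pse = pse, guess_gamma = 0, lapse_lambda = 0,
                        compliance = 1)
  expect_lt(response_probability(ob_g, "mixed.black.b2", 9),
            response_probability(ob_f, "mixed.black.b2", 9))
  # homogeneous conditions are untouched by compliance
  obc <- make_observer(pse = pse, compliance = 0.6)
  ob1 <- make_observer(pse = pse, compliance = 1)
  expect_equal(response_probability(obc, "homog_black.black.b2", 1.3),
               response_probability(ob1, "homog_black.black.b2", 1.3))
})

test_that("simulated responses are reproducible Bernoulli draws", {
  ob <- make_observer()
  draw_seq <- function(seed) with_preserved_seed(seed, {
    vapply(1:1000, function(i) simulate_response(ob, "mixed.black.b1", 1),
           logical(1))
  })
  expect_identical(draw_seq(7), draw_seq(7))
  # forced-certain response
  ob0 <- make_observer(guess_gamma = 0, lapse_lambda = 0)
  expect_true(all(with_preserved_seed(1, vapply(1:50, function(i)
    simulate_response(ob0, "homog_black.black.b1", 1e6), logical(1)))))
  # empirical rate within a 3-SE binomial band
  p <- response_probability(ob, "mixed.black.b1", 1)
  hits <- with_preserved_seed(11, mean(vapply(1:10000, function(i)
    simulate_response(ob, "mixed.black.b1", 1), logical(1))))
  expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("population draws respect the group configuration", {
  cfg0 <- population_config(n_observers = 4, between_sd = 0)
  pop0 <- make_population(cfg0, seed = 3)
  for (ob in pop0) expect_equal(ob$pse, cfg0$group_pse)
  cfg <- population_config(n_observers = 15, between_sd = 2)
  pop <- make_population(cfg, seed = 5)
  expect_length(pop, 15)
  expect_true(all(vapply(pop, function(o) length(o$pse) == 20, logical(1))))
  expect_true(all(vapply(pop, `[[`, numeric(1), "slope_sigma") >= 0.5))
  mat <- sapply(pop, `[[`, "pse")  # 20 x 15
  expect_true(all(abs(rowMeans(mat) - cfg$group_pse) <= 3 * 2 / sqrt(15)))
  expect_identical(sapply(make_population(cfg, seed = 5), `[[`, "pse"), mat)
})

test_that("the default group PSEs encode the canonical effect structure", {
  gp <- default_group_pse()
  for (b in 1:4) {
    expect_gt(gp[condition_id("homog_black", "black", b)],
              gp[condition_id("homog_white", "white", b)])
    expect_gt(gp[condition_id("mixed", "black", b)],
              gp[condition_id("mixed", "white", b)])
    expect_gt(abs(gp[condition_id("homog_black", "black", b)]),
              abs(gp[condition_id("mixed", "black", b)]))
  }
  expect_lt(gp[condition_id("mixed", "black", 5)],
            gp[condition_id("mixed", "white", 5)])  # reversal at extreme blur
  expect_silent(population_config())
  # a structure-violating configuration warns but is allowed (null exploration)
  flat <- setNames(rep(0, 20), condition_grid()$condition_id)
  expect_warning(population_config(group_pse = flat), "effect structure")
})

test_that("parameter validation rejects improper observers", {
  expect_error(make_observer(slope_sigma = 0), "positive")
  expect_error(make_observer(guess_gamma = 0.2), "0.1")
  expect_error(make_observer(compliance = 0.3), "0.5")
  expect_error(observer_params("x", setNames(rep(0, 3), c("a", "b", "c")), 3),
               "condition ids")
})
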