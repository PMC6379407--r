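# small deterministic PSE table: 4 observers, all 20 cells each
toy_table <- function(pse_fun, sigma_fun = function(o, id) 3) {
  grid <- condition_grid()
  do.call(rbind, lapply(1:4, function(o) {
    data.frame(observer_id = sprintf("obs%02d", o), grid[, 1:5],
               pse_weber_pct = vapply(grid$condition_id, pse_fun, numeric(1), o = o),
               sigma = vapply(grid$condition_id, sigma_fun, numeric(1), o = o),
               gamma = 0.02, lambda = 0.02, nll = 10, n_trials = 40,
               converged = TRUE, stringsAsFactors = FALSE, row.names = NULL)
  }))
}

test_that("difference scores subtract black-cued from white-cued PSEs", {
  tab <- toy_table(function(id, o) if (grepl("white", id)) -2 else 2)
  d <- difference_scores(tab, "mixed")
  expect_equal(nrow(d), 4 * 5)
  expect_true(all(d$diff_weber_pct == -4))
  dh <- difference_scores(tab, "homogeneous")
  expect_true(all(dh$diff_weber_pct == -4))
  tab0 <- toy_table(function(id, o) 1.5)
  expect_true(all(difference_scores(tab0, "mixed")$diff_weber_pct == 0))
  # a missing cell is named in the error
  miss <- tab[!(tab$observer_id == "obs02" &
                tab$condition_id == "mixed.white.b3"), ]
  expect_error(difference_scores(miss, "mixed"), "obs02.*blur 3.*white")
})

test_that("the JZS Bayes factor matches an independent oracle", {
  # zero-t case, frozen from the noncentral-t/Cauchy-mixture oracle
  x <- c(-7:7)  # mean 0 exactly -> t = 0, n = 15
  bf <- paired_bf10(x)
  expect_equal(bf$t_stat, 0)
  expect_equal(bf$bf10, 0.26235, tolerance = 1e-4)
  expect_equal(bf$bf10, oracle_bf10_nct(0, 15), tolerance = 1e-6)
  # agreement across a range of effect sizes and sample sizes
  set.seed(3)
  for (shift in c(-1.5, 0, 0.4, 2)) {
    for (n in c(5, 15, 40)) {
      got <- paired_bf10(rnorm(n, shift, 1))
      expect_equal(got$bf10, oracle_bf10_nct(got$t_stat, n), tolerance = 1e-6)
    }
  }
})

test_that("Bayes factors respect t-statistic symmetries", {
  x <- c(1.2, -0.4, 2.2, 0.3, -1.9, 0.7, 1.1, -0.2, 0.9, 1.4, 2.0, -0.8,
         0.1, 0.6, -1.1)
  y <- rev(x) * 0.7
  base <- paired_bf10(x, y)
  shifted <- paired_bf10(x + 3.14, y + 3.14)
  expect_equal(shifted$bf10, base$bf10, tolerance = 1e-10)
  # strictly increasing in |t| at fixed n
  tgrid <- seq(0, 6, by = 0.5)
  bfs <- vapply(tgrid, function(t) kanizsaPSE:::.jzs_bf10(t, 15, sqrt(2) / 2),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(kanizsaPSE:::.jzs_bf10(-2, 15, sqrt(2) / 2),
               kanizsaPSE:::.jzs_bf10(2, 15, sqrt(2) / 2), tolerance = 1e-10)
  expect_error(paired_bf10(rep(1, 10), rep(0, 10)), "zero-variance")
  expect_error(paired_bf10(1:2), "at least 3")
})

test_that("confidence intervals have Student-t width and correct coverage", {
  expect_equal(unname(ci95(rep(2.5, 6))), c(2.5, 2.5, 2.5))
  x <- rnorm(15)
  ci <- ci95(x)
  expect_equal(unname(ci["upper"] - ci["mean"]),
               qt(0.975, 14) * sd(x) / sqrt(15))  # multiplier ~2.1448
  covered <- with_preserved_seed(8, mean(vapply(1:2000, function(i) {
    ci <- ci95(rnorm(12, 1, 2))
    ci["lower"] <= 1 && 1 <= ci["upper"]
  }, logical(1))))
  expect_equal(covered, 0.95, tolerance = 0.02)
  expect_error(ci95(3), "at least 2")
})

test_that("slope comparisons flag incomputable cells instead of failing", {
  tab <- toy_table(function(id, o) 0, sigma_fun = function(o, id) 3)
  sc <- slope_comparison(tab)
  expect_equal(nrow(sc), 10)
  expect_true(all(is.na(sc$bf10)))
  expect_true(all(grepl("zero-variance", sc$note)))
  tab2 <- toy_table(function(id, o) 0,
                    sigma_fun = function(o, id) 3 + 0.3 * o +
                      0.1 * (o %% 2) * grepl("white", id))
  sc2 <- slope_comparison(tab2)
  expect_true(all(is.finite(sc2$bf10)))
})

test_that("the group summary assembles differences, slopes and the RM ANOVA", {
  set.seed(42)
  tab <- toy_table(function(id, o)
    (if (grepl("black", id)) 2 else -2) + rnorm(1, 0, 0.5),
    sigma_fun = function(o, id) 3 + 0.2 * o + rnorm(1, 0, 0.2))
  gs <- group_summary(tab)
  expect_equal(nrow(gs$differences), 10)
  expect_true(all(gs$differences$mean_diff >= gs$differences$ci95_low &
                  gs$differences$mean_diff <= gs$differences$ci95_high))
  expect_true(all(gs$differences$bf10 > 0))
  expect_setequal(gs$rm_anova$effect,
                  c("blur_level", "inducer_type", "blur_level:inducer_type"))
  f <- withr::local_tempfile(fileext = ".json")
  write_group_summary(gs, f)
  back <- jsonlite::read_json(f)
  expect_length(back$differences, 10)
})

test_that("evidence lands on the correct side under null and real effects", {
  # paired null: median BF over replicate experiments favours H0
  null_bfs <- with_preserved_seed(5, vapply(1:200, function(i)
    paired_bf10(rnorm(15, 0, 2), rnorm(15, 0, 2))$bf10, numeric(1)))
  expect_lt(median(null_bfs), 1)
  # a d = 2 separation is strong evidence most of the time
  alt_bfs <- with_preserved_seed(6, vapply(1:50, function(i)
    paired_bf10(rnorm(15, 2, 1), rnorm(15, 0, 1))$bf10, numeric(1)))
  expect_gt(mean(alt_bfs > 10), 0.8)
})
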