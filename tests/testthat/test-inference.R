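outcomes_fixture <- function(zips, values) {
  tibble::tibble(zip = as.character(zips), mean_fv = values)
}

test_that("relative ATT follows the ratio-of-pair-means definition", {
  pr <- fake_pairs(c("t1", "t2"), c("c1", "c2"))
  out <- outcomes_fixture(c("t1", "t2", "c1", "c2"),
                          c(1.03, 1.03, 1.00, 1.00))
  expect_equal(att_relative(pr, out, "mean_fv"), 3.0)

  out0 <- outcomes_fixture(c("t1", "t2", "c1", "c2"), c(1, 1, 1, 1))
  expect_equal(att_relative(pr, out0, "mean_fv"), 0.0)

  outneg <- outcomes_fixture(c("t1", "t2", "c1", "c2"),
                             c(0.9, 0.9, 1.0, 1.0))
  expect_equal(att_relative(pr, outneg, "mean_fv"), -10.0)

  # a reused control counts once per pair
  pr2 <- fake_pairs(c("t1", "t2"), c("c1", "c1"))
  out2 <- outcomes_fixture(c("t1", "t2", "c1"), c(2, 4, 2))
  expect_equal(att_relative(pr2, out2, "mean_fv"), 50)

  outz <- outcomes_fixture(c("t1", "t2", "c1", "c2"), c(1, 1, 1, -1))
  expect_error(att_relative(pr, outz, "mean_fv"), "control mean is zero")
})

test_that("matched-pair bootstrap is seeded, degenerate-safe and covers the estimate", {
  set.seed(15)
  n <- 60
  tz <- sprintf("t%02d", 1:n)
  cz <- sprintf("c%02d", 1:n)
  pr <- fake_pairs(tz, cz)
  out <- outcomes_fixture(c(tz, cz), c(rnorm(n, 1.05, 0.1), rnorm(n, 1, 0.1)))
  b1 <- bootstrap_pairs(pr, out, "mean_fv", reps = 500, seed = 7)
  b2 <- bootstrap_pairs(pr, out, "mean_fv", reps = 500, seed = 7)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$estimate)
  expect_gte(b1$ci_high, b1$estimate)
  expect_gte(b1$p_value, 1 / 500)
  expect_lte(b1$p_value, 1)

  # constant positive differences: point-mass CI and the p-value floor
  outc <- outcomes_fixture(c(tz, cz), rep(c(1.05, 1.00), each = n))
  bc <- bootstrap_pairs(pr, outc, "mean_fv", reps = 400, seed = 3)
  expect_equal(bc$ci_low, bc$estimate)
  expect_equal(bc$ci_high, bc$estimate)
  expect_equal(bc$p_value, 1 / 400)
})

test_that("paired t-test matches the closed form and flags degenerate input", {
  tz <- c("t1", "t2", "t3", "t4")
  cz <- c("c1", "c2", "c3", "c4")
  pr <- fake_pairs(tz, cz)
  # differences {+1, +1, +1, -1}: mean 0.5, sd 1, se 0.5 => t = 1, df = 3
  out <- outcomes_fixture(c(tz, cz), c(2, 2, 2, 0, 1, 1, 1, 1))
  tt <- paired_ttest(pr, out, "mean_fv")
  expect_equal(tt$t, 1.0)
  expect_equal(tt$df, 3)
  expect_equal(tt$p_value, 2 * (1 - pt(1, 3)))
  expect_false(tt$degenerate)

  # sign of t equals sign of the ATT numerator (shared numerator)
  expect_gt(att_relative(pr, out, "mean_fv"), 0)

  outz <- outcomes_fixture(c(tz, cz), rep(1, 8))
  expect_warning(ttz <- paired_ttest(pr, outz, "mean_fv"), "zero variance")
  expect_true(ttz$degenerate)
  expect_true(is.na(ttz$p_value))
})

test_that("Pearson reference correlation matches hand computations", {
  x <- 1:10
  expect_equal(correlate_reference(x, 2 * x + 1)$r, 1.0)
  expect_equal(correlate_reference(x, -x)$r, -1.0)
  # (0,0), (1,1), (2,0): correlation exactly 0
  z <- correlate_reference(c(0, 1, 2), c(0, 1, 0))
  expect_equal(z$r, 0)
  expect_equal(z$n, 3)
  # missing pairs are dropped before the n >= 3 check
  expect_equal(correlate_reference(c(x, NA), c(2 * x, 5))$n, 10)
  expect_error(correlate_reference(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate_reference(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("experiments estimate all outcomes with coherent intervals", {
  cfg <- sim_config(n_zips = 250, seed = 23)
  tab <- gen_zip_table(cfg)
  res <- run_experiment(tab$covariates, tab$outcomes, "college_frac",
                        reps = 300, seed = 5,
                        ga_pop_size = 25, ga_generations = 10)
  expect_s3_class(res$results, "tbl_df")
  expect_setequal(res$results$outcome,
                  c("mean_fv", "mean_fastfood", "mean_soda",
                    "overweight_fraction"))
  expect_true(all(res$results$ci_low_pct <= res$results$relative_diff_pct))
  expect_true(all(res$results$ci_high_pct >= res$results$relative_diff_pct))
  expect_true(res$balance$balanced)
  # bootstrap and t-test agree on rejection at the 5% level here
  expect_identical(res$results$p_value < 0.05, res$results$p_ttest < 0.05)
})

test_that("subgroup filters are applied before the split", {
  cfg <- sim_config(n_zips = 400, seed = 29)
  tab <- gen_zip_table(cfg)
  res <- run_experiment(tab$covariates, tab$outcomes, "income",
                        subgroup = "white_majority", reps = 200, seed = 5,
                        ga_pop_size = 20, ga_generations = 8)
  n_white <- sum(tab$covariates$frac_white >= 0.5)
  expect_equal(res$n_zips, n_white)
  # subgroup-specific median: the cut differs from the full-sample median
  expect_false(isTRUE(all.equal(res$cut, median(tab$covariates$income))))
  expect_error(
    run_experiment(tab$covariates[1:8, ], tab$outcomes[1:8, ], "income",
                   subgroup = "black_majority"),
    "too small|degenerate")
})

test_that("quartile splits amplify a monotone dose-response", {
  # outcomes rise continuously with grocery access, so comparing extreme
  # quarters must show a larger contrast than halves
  cfg <- sim_config(n_zips = 400, effects = list(), subgroup_effects = list(),
                    noise_sd = 0.02, seed = 37)
  cov <- gen_zip_covariates(cfg)
  dose <- rank(cov$grocery_access) / nrow(cov)
  set.seed(1)
  out <- tibble::tibble(
    zip = cov$zip,
    mean_fv = 1.0 * (1 + 0.10 * dose) * exp(rnorm(nrow(cov), 0, 0.02)),
    mean_fastfood = 0.35, mean_soda = 0.25, overweight_fraction = 0.5
  )
  est <- function(split) {
    run_experiment(cov, out, "grocery_access", split = split,
                   outcome_cols = "mean_fv", reps = 100, seed = 2,
                   ga_pop_size = 20, ga_generations = 8
    )$results$relative_diff_pct
  }
  expect_gt(abs(est("quartile")), abs(est("median")))
})

test_that("null experiments report correlations and detect real signals", {
  cfg <- sim_config(n_zips = 300, seed = 41)
  tab <- gen_zip_table(cfg)
  res <- null_experiment(tab$covariates, tab$outcomes, "service_frac",
                         reps = 300, seed = 9,
                         ga_pop_size = 25, ga_generations = 10)
  expect_named(res$null_correlations,
               c("income", "college_frac", "grocery_access",
                 "fastfood_access"))
  expect_true(all(abs(res$null_correlations) < 0.25))

  # inversion: a covariate that tracks the outcome itself must show an effect
  cov2 <- tab$covariates
  set.seed(2)
  cov2$service_frac <- rank(tab$outcomes$mean_fv) / nrow(cov2) +
    rnorm(nrow(cov2), 0, 0.05)
  res2 <- null_experiment(cov2, tab$outcomes, "service_frac",
                          reps = 300, seed = 9,
                          ga_pop_size = 25, ga_generations = 10)
  fv <- res2$results[res2$results$outcome == "mean_fv", ]
  expect_gt(fv$ci_low_pct, 0)
})
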