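test_that("the generator is fully deterministic given a seed", {
  cfg <- sim_config(n_zips = 80, participants_per_zip = 5,
                    active_days_mean = 15, seed = 101)
  a <- gen_zip_table(cfg)
  b <- gen_zip_table(cfg)
  expect_identical(a, b)
  ga <- gen_geography(a$covariates, cfg)
  gb <- gen_geography(b$covariates, cfg)
  expect_identical(ga, gb)
  la <- gen_food_logs(a$outcomes, cfg)
  lb <- gen_food_logs(b$outcomes, cfg)
  expect_identical(la, lb)
  # a different seed changes the draws
  cfg2 <- sim_config(n_zips = 80, participants_per_zip = 5,
                     active_days_mean = 15, seed = 102)
  expect_false(identical(gen_zip_table(cfg2)$covariates$income,
                         a$covariates$income))
})

test_that("covariate marginals sit at the study cut points and correlations converge", {
  cfg <- sim_config(n_zips = 2000, seed = 7)
  cov <- gen_zip_covariates(cfg)
  expect_lt(abs(median(cov$income) / 70241 - 1), 0.10)
  expect_lt(abs(median(cov$college_frac) - 0.298), 0.03)
  expect_lt(abs(median(cov$grocery_access) - 0.203), 0.03)
  expect_lt(abs(median(cov$fastfood_access) - 0.050), 0.02)
  expect_true(all(cov$college_frac > 0 & cov$college_frac < 1))
  expect_true(all(cov$ruca %in% 1:10))

  # latent correlations survive the marginal transforms: the Spearman
  # correlation of a Gaussian copula is (6/pi) asin(R/2)
  R <- default_covariate_correlation()
  vars <- rownames(R)
  S <- cor(apply(cov[, vars], 2, rank))
  expect_lt(max(abs(S - (6 / pi) * asin(R / 2))), 0.06)

  # majority composition near the configured probabilities
  p <- table(cov$majority) / nrow(cov)
  expect_lt(abs(p[["white"]] - 0.784), 0.04)
  expect_true(all(rowSums(cov[, c("frac_white", "frac_black",
                                  "frac_hispanic")]) <= 1 + 1e-9))
  maj <- cov$majority != "none"
  picked <- cbind(seq_len(nrow(cov)),
                  match(paste0("frac_", cov$majority),
                        c("frac_white", "frac_black", "frac_hispanic")))
  expect_true(all(as.matrix(cov[, c("frac_white", "frac_black",
                                    "frac_hispanic")])[picked[maj, ]] >= 0.5))
})

test_that("zero effects and zero noise give constant outcomes", {
  cfg <- sim_config(n_zips = 50, effects = list(), subgroup_effects = list(),
                    noise_sd = 0, seed = 3)
  tab <- gen_zip_table(cfg)
  for (oc in c("mean_fv", "mean_fastfood", "mean_soda",
               "overweight_fraction")) {
    expect_equal(diff(range(tab$outcomes[[oc]])), 0)
  }
})

test_that("ground truth composes overall and subgroup effects", {
  cfg <- sim_config(n_zips = 20, seed = 5)
  tab <- gen_zip_table(cfg)
  gt <- tab$ground_truth
  g <- function(f, sg, oc) {
    unname(gt$true_effect_pct[gt$factor == f & gt$subgroup == sg &
                                gt$outcome == oc])
  }
  expect_equal(g("grocery_access", "all", "mean_fv"), 3.4)
  expect_equal(g("college_frac", "all", "overweight_fraction"), -13.1)
  # Black-majority income effect reverses sign: 3.3 - 9.8 = -6.5
  expect_equal(g("income", "black_majority", "mean_fv"), -6.5)
  # subgroups without a configured modification inherit the overall effect
  expect_equal(g("income", "white_majority", "mean_fv"), 3.3)
})

test_that("injected treatment effects appear in the raw group contrast", {
  cfg <- sim_config(n_zips = 1000,
                    effects = list(grocery_access = c(mean_fv = 0.10)),
                    subgroup_effects = list(), noise_sd = 0.01, seed = 19)
  tab <- gen_zip_table(cfg)
  tr <- split_treatment(tab$covariates$grocery_access,
                        "high_is_treated")$role == "treated"
  contrast <- mean(tab$outcomes$mean_fv[tr]) /
    mean(tab$outcomes$mean_fv[!tr]) - 1
  expect_lt(abs(contrast - 0.10), 0.01)
  # untouched outcome shows no contrast
  c2 <- mean(tab$outcomes$mean_soda[tr]) /
    mean(tab$outcomes$mean_soda[!tr]) - 1
  expect_lt(abs(c2), 0.01)
})

test_that("classify + aggregate on generated logs recovers the zip outcomes", {
  cfg <- sim_config(n_zips = 2, participants_per_zip = 200, seed = 31)
  tab <- gen_zip_table(cfg)
  logs <- gen_food_logs(tab$outcomes, cfg)
  agg <- aggregate_cohort(logs$entries, logs$participants)
  expect_equal(nrow(agg$zips), 2)

  # the classifier must reproduce the generated counts exactly: every
  # rendered category string classifies into its category and no
  # distractor leaks in, so each participant's rate equals count / days
  re <- logs$realized[match(agg$participants$participant_id,
                            logs$realized$participant_id), ]
  expect_equal(agg$participants$active_days, as.integer(re$active_days))
  expect_equal(agg$participants$rate_fv, re$n_fv / re$active_days)
  expect_equal(agg$participants$rate_fastfood, re$n_fastfood / re$active_days)
  expect_equal(agg$participants$rate_soda, re$n_soda / re$active_days)

  # zip means sit near the latent targets, within sampling error: the
  # participant rates are Gamma(shape 4) around the zip mean, so the
  # zip-mean relative standard error is about 0.5 / sqrt(n); allow 4 SE
  got <- agg$zips[match(tab$outcomes$zip, agg$zips$zip), ]
  tol <- 4 * 0.5 / sqrt(min(got$n_participants))
  for (oc in c("mean_fv", "mean_fastfood", "mean_soda")) {
    expect_lt(max(abs(got[[oc]] / tab$outcomes[[oc]] - 1)), tol)
  }
  expect_lt(max(abs(got$overweight_fraction -
                      tab$outcomes$overweight_fraction)),
            4 * 0.5 / sqrt(min(got$n_participants)))
  # every active day has at least one entry and the volume is plausible
  expect_true(all(agg$participants$active_days >= 10))
})

test_that("juice-only logs yield zero F&V after the pipeline", {
  entries <- tibble::tibble(
    participant_id = "p1",
    log_date = rep(as.Date("2015-01-01") + 0:11, each = 2),
    brand = "Minute Maid",
    description = "Apple Juice",
    serving_unit = "cup",
    n_servings = 1
  )
  parts <- tibble::tibble(participant_id = "p1", zip = "00001", bmi = 24)
  agg <- aggregate_cohort(entries, parts, min_days = 10, min_participants = 1)
  expect_equal(agg$zips$mean_fv, 0)
  expect_equal(agg$zips$mean_soda, 0)
  expect_equal(agg$zips$mean_fastfood, 0)
})

test_that("geography round-trips through the environment stage", {
  cfg <- sim_config(n_zips = 30, seed = 43)
  cov <- gen_zip_covariates(cfg)
  geo <- gen_geography(cov, cfg)
  demo <- cov[, c("zip", "income", "college_frac", "service_frac",
                  "frac_white", "frac_black", "frac_hispanic", "majority",
                  "ruca", "population", "centroid_lat", "centroid_lon")]
  got <- build_zip_covariates(demo, geo$tracts, geo$crosswalk,
                              geo$businesses)
  expect_equal(got$zip, cov$zip)
  expect_lt(max(abs(got$grocery_access - cov$grocery_access)), 0.06)
  # fast-food shares match to binomial sampling error
  expect_lt(mean(abs(got$fastfood_access - cov$fastfood_access)), 0.02)
  expect_lt(max(abs(got$fastfood_access - cov$fastfood_access)), 0.08)
  expect_lt(mean(abs(got$food_desert_frac - cov$food_desert_frac)), 0.15)
})

test_that("configuration validation names offending correlation pairs", {
  R <- default_covariate_correlation()
  R["income", "college_frac"] <- R["college_frac", "income"] <- 1.4
  expect_error(sim_config(seed = 1, covariate_correlation = R),
               "income.*college_frac|college_frac.*income")
  R2 <- default_covariate_correlation()
  R2["income", "college_frac"] <- R2["college_frac", "income"] <- 0.99
  R2["income", "grocery_access"] <- R2["grocery_access", "income"] <- 0.99
  R2["college_frac", "grocery_access"] <-
    R2["grocery_access", "college_frac"] <- -0.99
  expect_error(sim_config(seed = 1, covariate_correlation = R2),
               "positive semidefinite")
  expect_error(sim_config(n_zips = 10), "seed")
})
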