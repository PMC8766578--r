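test_that("median split puts the boundary on the treated side", {
  s <- split_treatment(c(50000, 60000, 80000, 90000), "high_is_treated")
  expect_identical(s$role, c("control", "control", "treated", "treated"))

  # a value exactly at the cut is treated
  s2 <- split_treatment(c(1, 2, 3, 4, 5), "high_is_treated")
  expect_equal(s2$cut, 3)
  expect_identical(s2$role[3], "treated")

  # low_is_treated flips the side, boundary still treated
  s3 <- split_treatment(c(0.02, 0.08), "low_is_treated")
  expect_identical(s3$role, c("treated", "control"))
  s4 <- split_treatment(c(1, 2, 3), "low_is_treated")
  expect_identical(s4$role, c("treated", "treated", "control"))

  expect_error(split_treatment(rep(5, 4), "high_is_treated"), "degenerate")
})

test_that("quartile split keeps the extreme quarters and discards the middle", {
  v <- 1:8
  s <- split_treatment(v, "high_is_treated", "quartile")
  expect_identical(s$role[v >= s$cut[2]], rep("treated", sum(v >= s$cut[2])))
  expect_identical(s$role[v <= s$cut[1]], rep("control", sum(v <= s$cut[1])))
  expect_true(anyNA(s$role))
  s_lo <- split_treatment(v, "low_is_treated", "quartile")
  expect_identical(s_lo$role[1], "treated")
  expect_identical(s_lo$role[8], "control")
})

test_that("SMD uses the control-group SD and handles degenerate cases", {
  expect_equal(compute_smd(c(1, 2, 3), c(1, 2, 3)), 0)
  # unit case: mean difference 1 over control SD 1
  expect_equal(compute_smd(c(2.5, 3.5), 2 + c(-1, 0, 1)), 1)
  # treated {2,2}, control {1,3}: means equal, SMD 0
  expect_equal(compute_smd(c(2, 2), c(1, 3)), 0)
  # zero control SD with differing means: +Inf sentinel
  expect_equal(compute_smd(c(2, 2), c(1, 1)), Inf)
  expect_equal(compute_smd(c(1, 1), c(1, 1)), 0)
  expect_error(compute_smd(numeric(0), 1), "non-empty")
  # antisymmetry of the numerator at fixed control SD: shifting the treated
  # group to mirror the mean difference flips the sign exactly
  c1 <- c(1, 2, 3)
  t_hi <- c(4, 5, 6)            # mean difference +3
  t_lo <- c(-2, -1, 0)          # mean difference -3
  expect_equal(compute_smd(t_hi, c1), -compute_smd(t_lo, c1))
})

test_that("single-covariate matching equals plain nearest neighbour for any weight", {
  set.seed(21)
  zips <- tibble::tibble(zip = sprintf("%05d", 1:30), v1 = rnorm(30))
  treated <- rep(c(TRUE, FALSE), c(10, 20))
  for (wm in c(0.5, 100)) {
    cfg <- match_config("t", covariates = "v1", ga_pop_size = 5,
                        ga_generations = 2, weight_max = wm, seed = 4)
    m <- genetic_match(zips, treated, cfg)
    # oracle: per treated unit, the control with the smallest |v1| gap
    xt <- zips$v1[treated]
    xc <- zips$v1[!treated]
    exp_idx <- vapply(xt, function(v) which.min(abs(v - xc)), integer(1))
    expect_identical(m$pairs$control_zip,
                     zips$zip[!treated][exp_idx])
  }
})

test_that("genetic matching is deterministic and never worse than identity weights", {
  deck <- make_deck(12, 18, k = 3, seed = 8)
  cfg <- match_config("t", covariates = c("v1", "v2", "v3"),
                      ga_pop_size = 20, ga_generations = 8, seed = 99)
  m1 <- genetic_match(deck$zips, deck$treated, cfg)
  m2 <- genetic_match(deck$zips, deck$treated, cfg)
  expect_identical(m1, m2)

  # identity-weight baseline via the independent R oracle
  Z <- deck$Z
  xt <- Z[deck$treated, , drop = FALSE]
  xc <- Z[!deck$treated, , drop = FALSE]
  idx <- oracle_match(xt, xc, c(1, 1, 1))
  expect_lte(m1$fitness, oracle_fitness(xt, xc, idx) + 1e-12)
  # reported fitness agrees with the oracle recomputed on the returned pairs
  got_idx <- match(m1$pairs$control_zip, deck$zips$zip[!deck$treated])
  expect_equal(m1$fitness, oracle_fitness(xt, xc, got_idx))
})

test_that("on small decks the GA is at least as good as a dense grid search", {
  for (seed in 1:3) {
    deck <- make_deck(6, 8, k = 3, seed = seed)
    Z <- deck$Z
    xt <- Z[deck$treated, , drop = FALSE]
    xc <- Z[!deck$treated, , drop = FALSE]
    # brute-force grid over [0.1, 1]^3 at resolution 0.1 (weights are
    # scale-free, so this covers all weight ratios down to 10:1)
    grid <- as.matrix(expand.grid(w1 = seq(0.1, 1, 0.1),
                                  w2 = seq(0.1, 1, 0.1),
                                  w3 = seq(0.1, 1, 0.1)))
    grid_fit <- apply(grid, 1, function(w)
      oracle_fitness(xt, xc, oracle_match(xt, xc, w)))
    cfg <- match_config("t", covariates = c("v1", "v2", "v3"),
                        ga_pop_size = 30, ga_generations = 15,
                        weight_max = 100, seed = seed)
    m <- genetic_match(deck$zips, deck$treated, cfg)
    expect_lte(m$fitness, min(grid_fit) + 1e-12)
  }
})

test_that("matching with replacement ignores unmatched controls", {
  # tested at the kernel level with fixed weights and standardization:
  # at the package level, removing even an unused control changes the
  # full-sample SDs used to standardize, which rescales the metric
  deck <- make_deck(5, 10, k = 3, seed = 13)
  Z <- deck$Z
  xt <- Z[deck$treated, , drop = FALSE]
  xc <- Z[!deck$treated, , drop = FALSE]
  for (w in list(c(1, 1, 1), c(1, 2, 0.5))) {
    m <- dietscape:::nn_match_cpp(xt, xc, w, -1)
    unused <- setdiff(seq_len(nrow(xc)), m$match)
    expect_gt(length(unused), 0) # the deck must exercise the property
    drop_i <- unused[1]
    m2 <- dietscape:::nn_match_cpp(xt, xc[-drop_i, , drop = FALSE], w, -1)
    # control indices after the dropped row shift down by one
    expect_identical(m2$match, m$match - as.integer(m$match > drop_i))
    expect_equal(m2$distance, m$distance)
  }
})

test_that("the caliper drops an extreme treated outlier", {
  set.seed(31)
  n_c <- 20
  zips <- tibble::tibble(
    zip = sprintf("%05d", 1:(6 + n_c)),
    v1 = c(rnorm(5), 40, rnorm(n_c)), # unit 6 is far outside the cloud
    v2 = rnorm(6 + n_c)
  )
  treated <- rep(c(TRUE, FALSE), c(6, n_c))
  cfg <- match_config("t", covariates = c("v1", "v2"),
                      ga_pop_size = 10, ga_generations = 4, seed = 5)
  m_free <- genetic_match(zips, treated, cfg)
  expect_length(m_free$dropped_treated, 0)
  m_cal <- genetic_match(zips, treated, cfg, caliper = 2.0)
  expect_true(zips$zip[6] %in% m_cal$dropped_treated)
  expect_false(zips$zip[6] %in% m_cal$pairs$treated_zip)
})

test_that("adaptive caliper terminates balanced or raises, and skips when balanced", {
  cfg <- sim_config(n_zips = 200, seed = 17)
  tab <- gen_zip_table(cfg)
  mc <- match_config("grocery_access",
                     covariates = c("income", "college_frac",
                                    "fastfood_access"),
                     ga_pop_size = 25, ga_generations = 10, seed = 3)
  sp <- split_treatment(tab$covariates$grocery_access, "high_is_treated")
  fit <- adaptive_caliper_match(tab$covariates, sp$role == "treated", mc)
  expect_true(fit$balance$balanced)
  expect_lt(fit$balance$max_abs_smd, 0.25)
  # already balanced on the first pass: no caliper engaged
  expect_true(is.na(fit$match$caliper_used))
  expect_equal(fit$balance$n_pairs, sum(sp$role == "treated"))

  # impossible balance raises rather than returning an unbalanced match
  bad <- tibble::tibble(zip = c("t1", "t2", "c1", "c2"),
                        v1 = c(100, 101, 0, 1))
  bad_cfg <- match_config("t", covariates = "v1", ga_pop_size = 5,
                          ga_generations = 2, seed = 1)
  expect_error(adaptive_caliper_match(bad, c(TRUE, TRUE, FALSE, FALSE),
                                      bad_cfg),
               "balance unattainable")
})

test_that("balance report summarizes absolute SMDs", {
  deck <- make_deck(8, 12, k = 3, seed = 20)
  cfg <- match_config("t", covariates = c("v1", "v2", "v3"),
                      ga_pop_size = 10, ga_generations = 4, seed = 7)
  m <- genetic_match(deck$zips, deck$treated, cfg)
  rep_ <- balance_report(m)
  expect_equal(rep_$mean_smd, mean(abs(m$smd)))
  expect_equal(rep_$max_abs_smd, max(abs(m$smd)))
  expect_gte(rep_$mean_smd, 0)
  expect_identical(rep_$balanced, rep_$max_abs_smd < rep_$threshold)
  expect_equal(rep_$n_pairs, nrow(m$pairs))
})
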