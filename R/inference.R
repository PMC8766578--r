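#' The four study treatment factors
#'
#' @return Character vector of the zip-level factor column names studied
#'   as treatments: income, college education, grocery access and
#'   fast-food access.
#' @export
study_factors <- function() {
  c("income", "college_frac", "grocery_access", "fastfood_access")
}

#' Default treated-side convention for a study factor
#'
#' High income, high college education and high grocery access are
#' treated; LOW fast-food access is treated (less fast food nearby is the
#' "better" environment side).
#'
#' @param factor A factor name from [study_factors()].
#' @return `"high_is_treated"` or `"low_is_treated"`.
#' @export
default_direction <- function(factor) {
  if (factor == "fastfood_access") "low_is_treated" else "high_is_treated"
}

outcome_columns <- function() {
  c("mean_fv", "mean_fastfood", "mean_soda", "overweight_fraction")
}

# Outcome values for a vector of zips, in pair order (controls entering
# several pairs are counted once per pair).
outcome_by_zip <- function(outcomes, zips, outcome) {
  v <- outcomes[[outcome]][match(zips, as.character(outcomes$zip))]
  if (anyNA(v)) {
    stop("outcome '", outcome, "' missing for some matched zips",
         call. = FALSE)
  }
  v
}

#' ATT as a relative difference over matched pairs
#'
#' The average treatment effect on the treated, expressed as the relative
#' difference of the treated pair-mean to the control pair-mean:
#' `100 * (mean(treated) - mean(control)) / mean(control)` percent, with
#' means taken over pairs (reused controls counted once per pair). The
#' ratio-of-means form is robust to individual near-zero control values.
#'
#' @param match A `matched_pairs` object.
#' @param outcomes Zip-outcome table with a `zip` column.
#' @param outcome Outcome column name (e.g. `"mean_fv"`).
#' @return Relative difference in percent.
#' @export
att_relative <- function(match, outcomes, outcome) {
  tv <- outcome_by_zip(outcomes, match$pairs$treated_zip, outcome)
  cv <- outcome_by_zip(outcomes, match$pairs$control_zip, outcome)
  mc <- mean(cv)
  if (mc == 0) {
    stop("relative difference undefined: control mean is zero", call. = FALSE)
  }
  100 * (mean(tv) - mc) / mc
}

#' Matched-pair bootstrap for the relative ATT
#'
#' Resamples whole matched pairs (never individual zips) with replacement,
#' recomputes the relative ATT per replicate, and reports the 2.5/97.5
#' percentile confidence interval plus a two-sided sign-crossing p-value:
#' `p = 2 * min(frac of replicates <= 0, frac >= 0)`, floored at `1/reps`
#' and capped at 1. Replicates whose resampled control mean is exactly
#' zero are redrawn and counted.
#'
#' @inheritParams att_relative
#' @param reps Bootstrap replications (default 1000).
#' @param seed Integer seed.
#' @return List: `estimate` (point ATT), `ci_low`, `ci_high`, `p_value`
#'   (all percent), `reps`, `n_pairs`, `n_redrawn`.
#' @export
bootstrap_pairs <- function(match, outcomes, outcome, reps = 1000, seed = 1L) {
  tv <- outcome_by_zip(outcomes, match$pairs$treated_zip, outcome)
  cv <- outcome_by_zip(outcomes, match$pairs$control_zip, outcome)
  n <- length(tv)
  if (n < 2) stop("need at least 2 matched pairs to bootstrap", call. = FALSE)
  mc <- mean(cv)
  if (mc == 0) {
    stop("relative difference undefined: control mean is zero", call. = FALSE)
  }
  est <- 100 * (mean(tv) - mc) / mc
  set.seed(seed)
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
  mt <- rowMeans(matrix(tv[idx], nrow = reps))
  mcb <- rowMeans(matrix(cv[idx], nrow = reps))
  n_redrawn <- 0L
  while (any(bad <- mcb == 0)) {
    n_redrawn <- n_redrawn + sum(bad)
    idx2 <- matrix(sample.int(n, n * sum(bad), replace = TRUE), nrow = sum(bad))
    mt[bad] <- rowMeans(matrix(tv[idx2], nrow = sum(bad)))
    mcb[bad] <- rowMeans(matrix(cv[idx2], nrow = sum(bad)))
  }
  boot <- 100 * (mt - mcb) / mcb
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(1, max(1 / reps, p))
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], p_value = p,
       reps = reps, n_pairs = n, n_redrawn = n_redrawn)
}

#' Paired t-test cross-check on matched pairs
#'
#' Two-sided paired t-test on the treated-minus-control outcome
#' differences, used as a parametric cross-check of the bootstrap
#' p-values. Degenerate inputs (zero variance of pair differences) are
#' flagged with `p_value = NA`.
#'
#' @inheritParams att_relative
#' @return List: `p_value`, `t`, `df`, `degenerate` flag.
#' @export
paired_ttest <- function(match, outcomes, outcome) {
  tv <- outcome_by_zip(outcomes, match$pairs$treated_zip, outcome)
  cv <- outcome_by_zip(outcomes, match$pairs$control_zip, outcome)
  if (length(tv) < 2) stop("need at least 2 matched pairs", call. = FALSE)
  d <- tv - cv
  if (sd(d) == 0) {
    warning("zero variance of pair differences; t-test undefined",
            call. = FALSE)
    return(list(p_value = NA_real_, t = NA_real_,
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- t.test(tv, cv, paired = TRUE)
  list(p_value = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

# Subgroup filter: majority = group fraction >= 0.5 of the population.
apply_subgroup <- function(data, subgroup) {
  switch(subgroup,
         all = data,
         white_majority = filter(data, .data$frac_white >= 0.5),
         black_majority = filter(data, .data$frac_black >= 0.5),
         hispanic_majority = filter(data, .data$frac_hispanic >= 0.5),
         stop("unknown subgroup: ", subgroup, call. = FALSE))
}

#' Run one matching experiment (one treatment factor, all outcomes)
#'
#' The all-but-one-factor design: the zips are (optionally) restricted to
#' an ethnicity-majority subgroup, split into treated and control at the
#' factor's subgroup-specific median (or quartiles), matched one-to-one by
#' [adaptive_caliper_match()] on the *other* study factors, and the
#' relative ATT with matched-pair bootstrap CI and a paired t-test
#' cross-check is computed for each outcome.
#'
#' @param covariates Zip-covariate table (`zip`, the four study factors,
#'   ethnicity fractions, ...).
#' @param outcomes Zip-outcome table (`zip`, `mean_fv`, `mean_fastfood`,
#'   `mean_soda`, `overweight_fraction`).
#' @param factor Treatment factor column name.
#' @param direction Treated side; defaults to the study convention
#'   (high is treated, except low fast-food access).
#' @param match_covariates Covariates matched on; defaults to the other
#'   three study factors.
#' @param subgroup `"all"` (default), `"white_majority"`,
#'   `"black_majority"` or `"hispanic_majority"` (fraction >= 0.5),
#'   applied before the split so cut points are subgroup-specific.
#' @param split `"median"` (default) or `"quartile"`.
#' @param outcome_cols Outcomes to estimate (default all four).
#' @param reps Bootstrap replications (default 1000).
#' @param seed Integer seed driving both the matching search and the
#'   bootstrap.
#' @param ... Further arguments passed to [match_config()].
#' @return List of class `experiment_result`: `results` (tibble with one
#'   row per outcome: estimate, CI, bootstrap and t-test p-values,
#'   `n_pairs`), `match`, `balance`, `cut`, `factor`, `subgroup`, `n_zips`.
#' @export
run_experiment <- function(covariates, outcomes, factor,
                           direction = default_direction(factor),
                           match_covariates = setdiff(study_factors(), factor),
                           subgroup = "all",
                           split = "median",
                           outcome_cols = outcome_columns(),
                           reps = 1000, seed = 1L, ...) {
  data <- dplyr::inner_join(
    mutate(tibble::as_tibble(covariates), zip = as.character(.data$zip)),
    mutate(tibble::as_tibble(outcomes), zip = as.character(.data$zip)),
    by = "zip"
  )
  data <- apply_subgroup(data, subgroup)
  if (nrow(data) < 4) {
    stop("subgroup too small to analyse: ", nrow(data), " zip(s) in '",
         subgroup, "'", call. = FALSE)
  }
  sp <- split_treatment(data[[factor]], direction, split)
  keep <- !is.na(sp$role)
  data <- data[keep, , drop = FALSE]
  role <- sp$role[keep]
  if (sum(role == "treated") < 2 || sum(role == "control") < 2) {
    stop("subgroup too small to match: ", sum(role == "treated"),
         " treated, ", sum(role == "control"), " controls", call. = FALSE)
  }
  config <- match_config(treatment_factor = factor,
                         treatment_direction = direction,
                         split = split,
                         covariates = match_covariates,
                         seed = seed, ...)
  fit <- adaptive_caliper_match(data, role == "treated", config)
  results <- dplyr::bind_rows(lapply(outcome_cols, function(oc) {
    bs <- bootstrap_pairs(fit$match, data, oc, reps = reps, seed = seed)
    tt <- paired_ttest(fit$match, data, oc)
    tibble::tibble(
      factor = factor, subgroup = subgroup, outcome = oc,
      relative_diff_pct = bs$estimate,
      ci_low_pct = bs$ci_low, ci_high_pct = bs$ci_high,
      p_value = bs$p_value, p_ttest = tt$p_value,
      n_pairs = bs$n_pairs, bootstrap_reps = bs$reps
    )
  }))
  structure(
    list(results = results, match = fit$match, balance = fit$balance,
         cut = sp$cut, factor = factor, subgroup = subgroup,
         n_zips = nrow(data)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %s (%s), %d zips, %d pairs\n",
              x$factor, x$subgroup, x$n_zips, x$balance$n_pairs))
  print(as.data.frame(x$results[, c("outcome", "relative_diff_pct",
                                    "ci_low_pct", "ci_high_pct",
                                    "p_value")]), digits = 3)
  invisible(x)
}

#' Null-treatment discriminant-validity experiment
#'
#' Runs the full matching machinery with a covariate expected to be
#' unrelated to diet outcomes (e.g. the nearby fraction of countertop
#' installers) as the treatment factor, matching on the four study
#' factors. A trustworthy pipeline should return CIs covering zero. The
#' result carries a report of the null covariate's Pearson correlation
#' with each study factor, which should be small for a valid null.
#'
#' @inheritParams run_experiment
#' @param null_factor Column name of the null covariate.
#' @return An `experiment_result` with an extra `null_correlations`
#'   element (named vector of Pearson r against the study factors).
#' @export
null_experiment <- function(covariates, outcomes, null_factor,
                            direction = "high_is_treated",
                            subgroup = "all", split = "median",
                            reps = 1000, seed = 1L, ...) {
  cors <- vapply(study_factors(), function(f) {
    cor(covariates[[null_factor]], covariates[[f]])
  }, numeric(1))
  res <- run_experiment(covariates, outcomes, factor = null_factor,
                        direction = direction,
                        match_covariates = study_factors(),
                        subgroup = subgroup, split = split,
                        reps = reps, seed = seed, ...)
  res$null_correlations <- cors
  res
}

#' Pearson correlation against a reference series
#'
#' Validation helper comparing a pipeline-derived regional series against
#' an external reference (survey or purchase data): Pearson correlation
#' with a two-sided t-test p-value over the complete pairs.
#'
#' @param series_a,series_b Numeric vectors over the same regions
#'   (pairwise-complete; at least 3 complete pairs required).
#' @return List: `r`, `p_value`, `n`.
#' @export
correlate_reference <- function(series_a, series_b) {
  ok <- complete.cases(series_a, series_b)
  a <- series_a[ok]
  b <- series_b[ok]
  if (length(a) < 3) stop("need at least 3 paired regions", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance in a series; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
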