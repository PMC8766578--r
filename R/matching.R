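#' Matching configuration
#'
#' Bundles the treatment definition and the genetic-matching
#' hyperparameters. Defaults follow the study conventions: median split
#' with the boundary on the treated side, balance declared at all
#' per-covariate |SMD| < 0.25, and an adaptive caliper starting at 2.5
#' standardized units decreasing by 0.1.
#'
#' @param treatment_factor Covariate column defining treatment (e.g.
#'   `"income"`).
#' @param treatment_direction `"high_is_treated"` or `"low_is_treated"`
#'   (fast-food access uses the latter: *low* access is treated).
#' @param split `"median"` (default) or `"quartile"` (top vs bottom
#'   quartile, middle half discarded).
#' @param covariates Character vector of covariate columns matched on;
#'   must exclude the treatment factor.
#' @param balance_threshold Per-covariate |SMD| bound declaring balance
#'   (default 0.25).
#' @param caliper_start,caliper_step Adaptive caliper schedule in
#'   standardized units (defaults 2.5 and 0.1).
#' @param ga_pop_size,ga_generations Genetic-algorithm population size and
#'   generation count (defaults 50 and 30).
#' @param weight_max Upper bound of the covariate weight search space;
#'   weights live in `(0, weight_max]` (default 100).
#' @param seed Integer seed making the search reproducible.
#' @return A list of class `match_config`.
#' @export
match_config <- function(treatment_factor,
                         treatment_direction = c("high_is_treated",
                                                 "low_is_treated"),
                         split = c("median", "quartile"),
                         covariates,
                         balance_threshold = 0.25,
                         caliper_start = 2.5,
                         caliper_step = 0.1,
                         ga_pop_size = 50,
                         ga_generations = 30,
                         weight_max = 100,
                         seed = 1L) {
  treatment_direction <- match.arg(treatment_direction)
  split <- match.arg(split)
  stopifnot(balance_threshold > 0, caliper_start > caliper_step,
            caliper_step > 0, ga_pop_size >= 2, ga_generations >= 1,
            weight_max > 0, length(covariates) >= 1)
  if (treatment_factor %in% covariates) {
    stop("covariates must exclude the treatment factor", call. = FALSE)
  }
  structure(
    list(treatment_factor = treatment_factor,
         treatment_direction = treatment_direction,
         split = split,
         covariates = covariates,
         balance_threshold = balance_threshold,
         caliper_start = caliper_start,
         caliper_step = caliper_step,
         ga_pop_size = ga_pop_size,
         ga_generations = ga_generations,
         weight_max = weight_max,
         seed = as.integer(seed)),
    class = "match_config"
  )
}

#' Median or quartile treatment split
#'
#' Dichotomizes a continuous zip-level factor into treated and control
#' groups. Under a median split the boundary value is treated (treated =
#' `value >= median` when high is treated, `value <= median` when low is
#' treated); under a quartile split the top and bottom quartiles form the
#' groups and the middle half is discarded.
#'
#' @param values Numeric vector (one per zip); `NA` not allowed.
#' @param direction `"high_is_treated"` or `"low_is_treated"`.
#' @param split `"median"` or `"quartile"`.
#' @return List with `role` (character: `"treated"`, `"control"`, or `NA`
#'   for discarded middle units) and `cut` (the cut point, or the two
#'   quartile cut points).
#' @export
#' @examples
#' split_treatment(c(50000, 60000, 80000, 90000), "high_is_treated")
split_treatment <- function(values,
                            direction = c("high_is_treated",
                                          "low_is_treated"),
                            split = c("median", "quartile")) {
  direction <- match.arg(direction)
  split <- match.arg(split)
  if (anyNA(values)) stop("values must be non-missing", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 zips to split", call. = FALSE)
  if (diff(range(values)) == 0) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  if (split == "median") {
    cut <- median(values)
    treated <- if (direction == "high_is_treated") values >= cut else values <= cut
    role <- ifelse(treated, "treated", "control")
  } else {
    q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
    hi <- values >= q[2]
    lo <- values <= q[1]
    role <- rep(NA_character_, length(values))
    if (direction == "high_is_treated") {
      role[hi] <- "treated"
      role[lo] <- "control"
    } else {
      role[lo] <- "treated"
      role[hi] <- "control"
    }
    cut <- q
  }
  if (sum(role == "treated", na.rm = TRUE) == 0 ||
      sum(role == "control", na.rm = TRUE) == 0) {
    stop("degenerate split: empty treated or control group", call. = FALSE)
  }
  list(role = role, cut = cut)
}

#' Standardized mean difference with post-matching control SD
#'
#' `SMD = (mean(treated) - mean(control)) / sd(control)`, with the
#' *control-group* sample standard deviation as the denominator. Using the
#' post-matching control SD (typically smaller than the pooled pre-match
#' SD) gives a conservative balance reading. Degenerate cases: equal means
#' with zero control SD give 0; differing means with zero control SD give
#' the `Inf` sentinel.
#'
#' @param treated_values,control_values Non-empty numeric vectors.
#' @return The SMD (sign follows the mean difference).
#' @export
compute_smd <- function(treated_values, control_values) {
  if (length(treated_values) == 0 || length(control_values) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  num <- mean(treated_values) - mean(control_values)
  s <- if (length(control_values) > 1) sd(control_values) else 0
  if (s == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / s
  }
}

# Per-covariate SMD of a matched sample: treated rows vs their matched
# controls (controls counted once per pair). Matrices are row-aligned.
matched_smds <- function(xt_matched, xc_matched) {
  vapply(seq_len(ncol(xt_matched)), function(m) {
    compute_smd(xt_matched[, m], xc_matched[, m])
  }, numeric(1))
}

# GA fitness for a population of weight vectors (rows of W): mean
# absolute SMD across covariates of the induced match, evaluated in
# compiled code. +Inf when the caliper leaves nothing matched.
population_fitness <- function(W, xt, xc, caliper) {
  ga_fitness_cpp(xt, xc, W, caliper)
}

#' One-to-one genetic matching with replacement
#'
#' Matches each treated zip to its nearest control (with replacement)
#' under a weighted Euclidean distance on covariates standardized by the
#' full-sample mean and SD. The covariate weights are tuned by a genetic
#' algorithm (tournament selection, uniform crossover, multiplicative
#' log-normal mutation, elitism) whose fitness is the mean absolute SMD
#' across covariates of the resulting match — the balance the matching
#' exists to optimize. The identity weight vector is seeded into the
#' initial population, so the result is never worse-balanced than plain
#' equal-weight nearest-neighbour matching. The estimand is the average
#' treatment effect on the treated (ATT): every treated unit keeps its
#' match (unless a caliper drops it), controls may be reused.
#'
#' @param zips Data frame with a `zip` column and the covariate columns in
#'   `config$covariates` (no missing values).
#' @param treated Logical vector along `zips` rows: `TRUE` = treated.
#' @param config A [match_config()].
#' @param caliper Optional per-covariate caliper in standardized units
#'   (`NULL` = none); treated units with no control inside the caliper on
#'   every covariate are dropped.
#' @return An object of class `matched_pairs`: list with `pairs` (tibble
#'   `treated_zip`, `control_zip`, `distance`), `dropped_treated`,
#'   `weights`, `caliper_used`, `fitness`, `smd` (named per-covariate SMD
#'   vector of the returned match) and `config`.
#' @export
genetic_match <- function(zips, treated, config, caliper = NULL) {
  stopifnot(is.logical(treated), length(treated) == nrow(zips),
            "zip" %in% names(zips),
            all(config$covariates %in% names(zips)))
  if (!any(treated)) stop("no treated units", call. = FALSE)
  if (!any(!treated)) stop("no control units", call. = FALSE)
  X <- as.matrix(zips[, config$covariates, drop = FALSE])
  if (anyNA(X)) stop("covariates must be non-missing", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate covariate(s): ",
         paste(config$covariates[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X) # full-sample standardization for the distance metric
  xt <- Z[treated, , drop = FALSE]
  xc <- Z[!treated, , drop = FALSE]
  k <- ncol(Z)
  cal <- if (is.null(caliper)) -1 else caliper

  set.seed(config$seed)
  w_max <- config$weight_max
  w_min <- w_max / 1e4
  n_pop <- config$ga_pop_size
  # log-uniform initial weights, identity vector included
  pop <- matrix(exp(runif(n_pop * k, log(w_min), log(w_max))), nrow = n_pop)
  pop[1, ] <- 1
  ev <- population_fitness(pop, xt, xc, cal)
  fit <- ev$fitness

  for (gen in seq_len(config$ga_generations)) {
    ord <- order(fit)
    elite_idx <- ord[seq_len(min(2, n_pop))]
    new_pop <- pop[elite_idx, , drop = FALSE]
    while (nrow(new_pop) < n_pop) {
      pick <- function() {
        cand <- sample.int(n_pop, 2)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      cross <- runif(k) < 0.5
      child <- ifelse(cross, p1, p2)
      mut <- runif(k) < 0.3
      child[mut] <- pmin(w_max, pmax(w_min, child[mut] * exp(rnorm(sum(mut), 0, 0.7))))
      new_pop <- rbind(new_pop, child)
    }
    pop <- new_pop
    ev <- population_fitness(pop, xt, xc, cal)
    fit <- ev$fitness
  }

  best_i <- which.min(fit)
  w_best <- pop[best_i, ]
  best_nn <- nn_match_cpp(xt, xc, w_best, cal)
  if (all(is.na(best_nn$match))) {
    stop("caliper dropped every treated unit; no match possible", call. = FALSE)
  }
  best <- list(fitness = fit[best_i], smd = ev$smd[best_i, ],
               match = best_nn$match, distance = best_nn$distance)
  treated_zip <- as.character(zips$zip[treated])
  control_zip <- as.character(zips$zip[!treated])
  keep <- !is.na(best$match)
  structure(
    list(
      pairs = tibble::tibble(
        treated_zip = treated_zip[keep],
        control_zip = control_zip[best$match[keep]],
        distance = best$distance[keep]
      ),
      dropped_treated = treated_zip[!keep],
      weights = setNames(w_best, config$covariates),
      caliper_used = if (is.null(caliper)) NA_real_ else caliper,
      fitness = best$fitness,
      smd = setNames(best$smd, config$covariates),
      config = config
    ),
    class = "matched_pairs"
  )
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat("Matched pairs:", nrow(x$pairs), "pairs,",
      length(x$dropped_treated), "treated dropped",
      if (!is.na(x$caliper_used)) sprintf("(caliper %.1f)", x$caliper_used)
      else "(no caliper)", "\n")
  cat("  mean |SMD| =", format(x$fitness, digits = 3),
      " max |SMD| =", format(max(abs(x$smd)), digits = 3), "\n")
  invisible(x)
}

#' Balance diagnostics for a matched sample
#'
#' Summarizes the per-covariate standardized mean differences of a match.
#' Balance is declared when every covariate's |SMD| is below the
#' threshold.
#'
#' @param match A `matched_pairs` object.
#' @param threshold Balance bound (defaults to the match config's).
#' @return List of class `balance_report`: `smd_per_covariate`,
#'   `mean_smd`, `median_smd`, `max_abs_smd` (all on absolute SMDs except
#'   the signed per-covariate vector), `balanced`, `threshold`, `n_pairs`,
#'   `n_dropped`.
#' @export
balance_report <- function(match, threshold = match$config$balance_threshold) {
  abs_smd <- abs(match$smd)
  structure(
    list(
      smd_per_covariate = match$smd,
      mean_smd = mean(abs_smd),
      median_smd = median(abs_smd),
      max_abs_smd = max(abs_smd),
      balanced = max(abs_smd) < threshold,
      threshold = threshold,
      n_pairs = nrow(match$pairs),
      n_dropped = length(match$dropped_treated)
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance:", if (x$balanced) "OK" else "NOT balanced",
      sprintf("(max |SMD| %.3f vs threshold %.2f; %d pairs, %d dropped)\n",
              x$max_abs_smd, x$threshold, x$n_pairs, x$n_dropped))
  invisible(x)
}

#' Genetic matching with an adaptive caliper
#'
#' Runs [genetic_match()] without a caliper first. If any covariate's
#' |SMD| reaches the balance threshold, re-runs with a per-covariate
#' caliper starting at `caliper_start` standardized units and decreasing
#' by `caliper_step` until balance is achieved; treated units with no
#' control inside the caliper are dropped (shifting the estimand toward a
#' caliper-restricted ATT, which the report discloses via the dropped
#' count). Errors if the caliper reaches zero without balance.
#'
#' @inheritParams genetic_match
#' @return List with elements `match` (`matched_pairs`) and `balance`
#'   (`balance_report`).
#' @export
adaptive_caliper_match <- function(zips, treated, config) {
  m <- genetic_match(zips, treated, config, caliper = NULL)
  rep_ <- balance_report(m)
  if (rep_$balanced) {
    return(list(match = m, balance = rep_))
  }
  caliper <- config$caliper_start
  while (caliper > 0) {
    m <- tryCatch(genetic_match(zips, treated, config, caliper = caliper),
                  error = function(e) NULL)
    if (!is.null(m)) {
      rep_ <- balance_report(m)
      if (rep_$balanced) {
        return(list(match = m, balance = rep_))
      }
    }
    caliper <- caliper - config$caliper_step
  }
  stop("balance unattainable: caliper exhausted without |SMD| < ",
       config$balance_threshold, call. = FALSE)
}
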