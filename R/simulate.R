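#' Default cross-correlation of the simulated zip covariates
#'
#' Latent Gaussian correlations used by the copula in
#' [gen_zip_covariates()]. Income and college education are strongly
#' related; both relate moderately to grocery access; fast-food and
#' grocery access co-vary (both track urbanicity); the null-treatment
#' covariate (`service_frac`, the nearby share of home-service businesses)
#' is uncorrelated with everything by construction.
#'
#' @return A 5x5 correlation matrix with dimnames `income`,
#'   `college_frac`, `grocery_access`, `fastfood_access`, `service_frac`.
#' @export
default_covariate_correlation <- function() {
  nm <- c("income", "college_frac", "grocery_access", "fastfood_access",
          "service_frac")
  R <- diag(5)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("income", "college_frac", 0.60)
  set_r("income", "grocery_access", 0.25)
  set_r("income", "fastfood_access", -0.15)
  set_r("college_frac", "grocery_access", 0.20)
  set_r("college_frac", "fastfood_access", -0.10)
  set_r("grocery_access", "fastfood_access", 0.35)
  R
}

#' Default injected treatment effects
#'
#' Relative effects (as fractions) of each above/below-median treatment on
#' each outcome, used as the generator's ground truth. The default values
#' reproduce the headline study conditions: e.g. high grocery access
#' raises F&V consumption by 3.4% and lowers fast food by 7.6%; high
#' educational attainment lowers the overweight/obesity fraction by 13.1%.
#'
#' @return Named list `factor -> named numeric over outcomes`.
#' @export
default_effects <- function() {
  list(
    grocery_access = c(mean_fv = 0.034, mean_fastfood = -0.076,
                       mean_soda = -0.064, overweight_fraction = -0.024),
    fastfood_access = c(mean_fv = 0.053, mean_fastfood = -0.062,
                        mean_soda = -0.133, overweight_fraction = -0.015),
    college_frac = c(mean_fv = 0.092, mean_fastfood = -0.085,
                     mean_soda = -0.138, overweight_fraction = -0.131),
    income = c(mean_fv = 0.033, mean_fastfood = -0.068,
               mean_soda = -0.086, overweight_fraction = 0.006)
  )
}

#' Default subgroup-specific effect modifications
#'
#' Additional relative effects applied on top of [default_effects()] when
#' a zip belongs to an ethnicity-majority subgroup, emulating the observed
#' heterogeneity: income effects reverse direction in Black-majority zips
#' (the "diminishing returns" pattern), and grocery access helps F&V
#' consumption substantially more in Black- and Hispanic-majority zips.
#'
#' @return Named list `subgroup -> factor -> named numeric over outcomes`.
#' @export
default_subgroup_effects <- function() {
  list(
    black_majority = list(
      income = c(mean_fv = -0.098, mean_fastfood = 0.123,
                 mean_soda = 0.227, overweight_fraction = 0.075),
      grocery_access = c(mean_fv = 0.068, mean_fastfood = -0.050,
                         mean_soda = 0.011, overweight_fraction = -0.066),
      fastfood_access = c(mean_fastfood = -0.058,
                          overweight_fraction = 0.046),
      college_frac = c(mean_fv = 0.020)
    ),
    hispanic_majority = list(
      income = c(mean_fv = 0.024),
      grocery_access = c(mean_fv = 0.040),
      college_frac = c(mean_soda = -0.027, overweight_fraction = -0.006)
    )
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults encode
#' the study conditions: about 9.30 logged entries per participant-day, a
#' mean of 197 active days with a hard minimum around 10, 30+ participants
#' per included zip, a zip composition of 78.4% white-majority, 5.6%
#' Hispanic-majority and 3.7% Black-majority, marginals whose medians sit
#' at the study cut points (income $70,241; college 29.8%; grocery access
#' 20.3%; fast-food share 5.0%), and the headline relative treatment
#' effects as ground truth.
#'
#' @param n_zips Number of zip codes (default 500).
#' @param participants_per_zip Participants simulated per zip (default 40).
#' @param entries_per_day_mean Mean total log entries per active day
#'   (default 9.30).
#' @param active_days_mean Mean active days per participant (default 197;
#'   negative-binomial above a minimum of 10).
#' @param covariate_correlation Latent copula correlation matrix (see
#'   [default_covariate_correlation()]).
#' @param effects,subgroup_effects Injected relative effects (fractions);
#'   see [default_effects()] and [default_subgroup_effects()].
#' @param noise_sd SD of the multiplicative log-normal outcome noise
#'   (default 0.05).
#' @param baseline_outcomes Baseline outcome levels for an untreated,
#'   no-majority zip: mean daily F&V / fast-food / soda entries and the
#'   overweight fraction.
#' @param majority_probs Sampling probabilities of the zip majority type.
#' @param bmi_sd Within-zip SD of participant BMI (default 4).
#' @param bmi_missing_rate Probability a participant does not report BMI
#'   (default 0.0008, i.e. 99.92% reporting).
#' @param restaurants_per_zip,other_businesses_per_zip Poisson means of
#'   simulated business counts near each centroid.
#' @param seed Integer seed (mandatory); every generator call derives its
#'   stream from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_zips = 500,
                       participants_per_zip = 40,
                       entries_per_day_mean = 9.30,
                       active_days_mean = 197,
                       covariate_correlation = default_covariate_correlation(),
                       effects = default_effects(),
                       subgroup_effects = default_subgroup_effects(),
                       noise_sd = 0.05,
                       baseline_outcomes = c(mean_fv = 1.2,
                                             mean_fastfood = 0.35,
                                             mean_soda = 0.25,
                                             overweight_fraction = 0.55),
                       majority_probs = c(white = 0.784, hispanic = 0.056,
                                          black = 0.037, none = 0.123),
                       bmi_sd = 4,
                       bmi_missing_rate = 0.0008,
                       restaurants_per_zip = 150,
                       other_businesses_per_zip = 50,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  R <- covariate_correlation
  if (!isTRUE(all.equal(R, t(R))) || any(diag(R) != 1)) {
    stop("covariate_correlation must be a symmetric correlation matrix",
         call. = FALSE)
  }
  off <- abs(R[upper.tri(R)]) > 1
  if (any(off)) {
    idx <- which(upper.tri(R), arr.ind = TRUE)[off, , drop = FALSE]
    stop("correlation out of [-1, 1] for pair (",
         rownames(R)[idx[1, 1]], ", ", colnames(R)[idx[1, 2]], ")",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("covariate_correlation is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(ev), digits = 3), ")",
         call. = FALSE)
  }
  stopifnot(n_zips >= 2, participants_per_zip >= 1,
            entries_per_day_mean > 0, active_days_mean > 10,
            noise_sd >= 0, all(baseline_outcomes > 0),
            abs(sum(majority_probs) - 1) < 1e-8)
  structure(
    list(n_zips = as.integer(n_zips),
         participants_per_zip = as.integer(participants_per_zip),
         entries_per_day_mean = entries_per_day_mean,
         active_days_mean = active_days_mean,
         covariate_correlation = R,
         effects = effects,
         subgroup_effects = subgroup_effects,
         noise_sd = noise_sd,
         baseline_outcomes = baseline_outcomes,
         majority_probs = majority_probs,
         bmi_sd = bmi_sd,
         bmi_missing_rate = bmi_missing_rate,
         restaurants_per_zip = restaurants_per_zip,
         other_businesses_per_zip = other_businesses_per_zip,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Gaussian draws with a target correlation structure (copula latents).
copula_draws <- function(n, R) {
  L <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(rnorm(n * nrow(R)), nrow = n) %*% L
  colnames(Z) <- colnames(R)
  Z
}

#' Generate the synthetic zip-covariate table
#'
#' Draws zip-level covariates from a Gaussian copula with the configured
#' latent correlations and maps them to realistic marginals: log-normal
#' income with median $70,241, logistic-transformed fractions with medians
#' at the study cut points (college 29.8%, grocery access 20.3%, fast-food
#' share 5.0%, null covariate 3%). Ethnicity-majority type is sampled per
#' the configured composition, income is shifted down in Black- and
#' Hispanic-majority zips (realistic confounding for the matching to
#' remove), a food-desert fraction is derived anti-correlated with grocery
#' access, and rural-urban (RUCA) codes, population and well-separated
#' centroid coordinates are attached.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per zip: `zip`, the four study factors,
#'   `service_frac` (null covariate), `food_desert_frac`, ethnicity
#'   fractions, `majority`, `ruca`, `population`, `centroid_lat`,
#'   `centroid_lon`.
#' @export
gen_zip_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_zips

  majority <- sample(names(config$majority_probs), n, replace = TRUE,
                     prob = config$majority_probs)
  Z <- copula_draws(n, config$covariate_correlation)
  z_inc <- Z[, "income"] - 0.7 * (majority == "black") -
    0.5 * (majority == "hispanic")

  fracs <- t(vapply(majority, function(m) {
    if (m == "none") {
      repeat {
        w <- rgamma(4, shape = 2)
        w <- w / sum(w)
        if (all(w < 0.5)) break
      }
      w[1:3]
    } else {
      main <- runif(1, 0.5, 0.9)
      rest <- rgamma(3, shape = 1)
      rest <- rest / sum(rest) * (1 - main)
      out <- c(white = rest[1], black = rest[2], hispanic = rest[3])
      out[m] <- main
      out
    }
  }, numeric(3)))
  colnames(fracs) <- c("frac_white", "frac_black", "frac_hispanic")

  # RUCA codes skewed urban (codes 7-10 = rural, underrepresented)
  ruca <- sample(1:10, n, replace = TRUE,
                 prob = c(0.35, 0.12, 0.10, 0.08, 0.06, 0.05,
                          0.07, 0.07, 0.05, 0.05))

  # jittered grid of centroids over the continental US, spaced so that
  # neighbouring zips' 40 km business queries do not overlap
  nx <- ceiling(sqrt(n * 2))
  ny <- ceiling(n / nx)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))[seq_len(n), ]
  lon <- -124 + (grid$ix - 0.5) * (57 / nx) + runif(n, -0.1, 0.1)
  lat <- 25 + (grid$iy - 0.5) * (23 / ny) + runif(n, -0.1, 0.1)

  tibble::tibble(
    zip = sprintf("%05d", seq_len(n)),
    income = exp(log(70241) + 0.5 * z_inc),
    college_frac = plogis(qlogis(0.298) + 0.8 * Z[, "college_frac"]),
    grocery_access = plogis(qlogis(0.203) + 1.0 * Z[, "grocery_access"]),
    fastfood_access = plogis(qlogis(0.050) + 0.8 * Z[, "fastfood_access"]),
    service_frac = plogis(qlogis(0.030) + 0.8 * Z[, "service_frac"]),
    food_desert_frac = plogis(qlogis(0.20) - 2.0 * Z[, "grocery_access"] +
                                rnorm(n, 0, 0.5)),
    frac_white = fracs[, "frac_white"],
    frac_black = fracs[, "frac_black"],
    frac_hispanic = fracs[, "frac_hispanic"],
    majority = majority,
    ruca = ruca,
    population = round(exp(log(7872) + rnorm(n, 0, 0.7))),
    centroid_lat = lat,
    centroid_lon = lon
  )
}

#' Generate zip outcomes with known injected effects
#'
#' Computes each zip's outcome as
#' `baseline * (1 + sum_f delta_f T_f + sum_f delta_(g,f) T_f) * exp(eps)`
#' with `eps ~ Normal(0, noise_sd)`: multiplicative treatment effects on a
#' common baseline, treatment indicators `T_f` from median splits of the
#' generated covariates (study directions: high income / college / grocery
#' treated, low fast-food access treated), subgroup modifications applied
#' in ethnicity-majority zips, and log-normal noise. The overweight
#' fraction is clipped to `[0.01, 0.99]`.
#'
#' @param covariates Table from [gen_zip_covariates()].
#' @param config A [sim_config()]; `config$effects` and
#'   `config$subgroup_effects` define the truth.
#' @param seed Seed for the outcome noise (default `config$seed + 1`, so
#'   regenerating outcomes under different effects reuses the same noise
#'   stream).
#' @return List: `outcomes` (tibble `zip`, `n_participants` placeholder,
#'   four outcome columns) and `ground_truth` (tibble `factor`,
#'   `subgroup`, `outcome`, `true_effect_pct`).
#' @export
gen_zip_outcomes <- function(covariates, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- nrow(covariates)
  oc <- outcome_columns()

  treat <- vapply(study_factors(), function(f) {
    split_treatment(covariates[[f]], default_direction(f))$role == "treated"
  }, logical(n))

  mult <- matrix(1, nrow = n, ncol = length(oc), dimnames = list(NULL, oc))
  for (f in names(config$effects)) {
    eff <- config$effects[[f]]
    for (o in names(eff)) {
      mult[, o] <- mult[, o] + eff[[o]] * treat[, f]
    }
  }
  for (g in names(config$subgroup_effects)) {
    g_short <- sub("_majority$", "", g)
    in_g <- covariates$majority == g_short
    for (f in names(config$subgroup_effects[[g]])) {
      eff <- config$subgroup_effects[[g]][[f]]
      for (o in names(eff)) {
        mult[, o] <- mult[, o] + eff[[o]] * treat[, f] * in_g
      }
    }
  }

  out <- tibble::tibble(zip = as.character(covariates$zip))
  for (o in oc) {
    noise <- exp(rnorm(n, 0, config$noise_sd))
    out[[o]] <- config$baseline_outcomes[[o]] * mult[, o] * noise
  }
  out$overweight_fraction <- pmin(0.99, pmax(0.01, out$overweight_fraction))

  gt <- dplyr::bind_rows(lapply(
    c("all", "white_majority", "black_majority", "hispanic_majority"),
    function(sg) {
      dplyr::bind_rows(lapply(study_factors(), function(f) {
        base_eff <- config$effects[[f]]
        extra <- if (sg %in% names(config$subgroup_effects)) {
          config$subgroup_effects[[sg]][[f]]
        } else {
          NULL
        }
        tibble::tibble(
          factor = f, subgroup = sg, outcome = oc,
          true_effect_pct = 100 * vapply(oc, function(o) {
            e <- if (!is.null(base_eff) && o %in% names(base_eff))
              base_eff[[o]] else 0
            if (!is.null(extra) && o %in% names(extra))
              e <- e + extra[[o]]
            e
          }, numeric(1))
        )
      }))
    }
  ))
  list(outcomes = out, ground_truth = gt)
}

#' Generate the full synthetic zip table
#'
#' Convenience wrapper: [gen_zip_covariates()] then [gen_zip_outcomes()].
#'
#' @param config A [sim_config()].
#' @return List: `covariates`, `outcomes`, `ground_truth`.
#' @export
gen_zip_table <- function(config) {
  covariates <- gen_zip_covariates(config)
  res <- gen_zip_outcomes(covariates, config)
  list(covariates = covariates, outcomes = res$outcomes,
       ground_truth = res$ground_truth)
}
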