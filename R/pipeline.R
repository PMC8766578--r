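config_defaults <- function() {
  list(
    seed = NULL, # mandatory, no default
    outdir = NULL, # default: tempdir per run
    n_zips = 500,
    participants_per_zip = 40,
    entries_per_day_mean = 9.30,
    active_days_mean = 197,
    noise_sd = 0.05,
    min_days = 10,
    min_participants = 30,
    balance_threshold = 0.25,
    caliper_start = 2.5,
    caliper_step = 0.1,
    bootstrap_reps = 1000,
    ga_pop_size = 50,
    ga_generations = 30,
    weight_max = 100,
    split = "median",
    factors = c("income", "college_frac", "grocery_access",
                "fastfood_access"),
    subgroups = "all",
    run_null = TRUE,
    null_factor = "service_frac"
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON or YAML configuration file, applies the study defaults
#' (minimum 10 active days, 30 participants per zip, balance threshold
#' 0.25, caliper 2.5 decreasing by 0.1, 1000 bootstrap replications) and
#' validates the schema. Unknown keys are rejected by name; `seed` is
#' mandatory.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param config A named list of configuration overrides (possibly empty).
#' @export
validate_config <- function(config = list()) {
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("configuration requires 'seed'", call. = FALSE)
  check <- function(ok, key, constraint) {
    if (!isTRUE(ok)) {
      stop("configuration key '", key, "' violates: ", constraint,
           call. = FALSE)
    }
  }
  check(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed),
        "seed", "integer")
  check(cfg$n_zips >= 2, "n_zips", ">= 2")
  check(cfg$participants_per_zip >= 1, "participants_per_zip", ">= 1")
  check(cfg$entries_per_day_mean > 0, "entries_per_day_mean", "> 0")
  check(cfg$active_days_mean > 10, "active_days_mean", "> 10")
  check(cfg$noise_sd >= 0, "noise_sd", ">= 0")
  check(cfg$min_days >= 1, "min_days", ">= 1")
  check(cfg$min_participants >= 1, "min_participants", ">= 1")
  check(cfg$balance_threshold > 0, "balance_threshold", "> 0")
  check(cfg$caliper_start > cfg$caliper_step && cfg$caliper_step > 0,
        "caliper_start/caliper_step", "caliper_start > caliper_step > 0")
  check(cfg$bootstrap_reps >= 2, "bootstrap_reps", ">= 2")
  check(cfg$split %in% c("median", "quartile"), "split",
        "one of median, quartile")
  check(all(cfg$factors %in% study_factors()), "factors",
        "subset of the four study factors")
  check(all(cfg$subgroups %in% c("all", "white_majority", "black_majority",
                                 "hispanic_majority")),
        "subgroups", "known subgroup names")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Write a configuration back to disk
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, path))`
#' round-trips to an identical configuration.
#'
#' @param config A `pipeline_config`.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

write_stage_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  path
}

#' Run the full pipeline end to end
#'
#' Executes simulate (zip tables, geography, food logs) → classify →
#' aggregate → environment → one matching experiment per configured
#' factor and subgroup → optional null-treatment check, writing every
#' inter-stage CSV, a results JSON and a run manifest into `outdir`. The
#' matching stage consumes the *pipeline-derived* tables: outcomes
#' re-aggregated from the simulated food logs and food-environment
#' covariates recomputed from the simulated geography, so the whole chain
#' is exercised. Each stage logs record counts in and out, keeping the
#' filter attrition visible. Fails fast on stage errors; the manifest
#' records the stages completed.
#'
#' @param config A `pipeline_config`, or a path to a config file.
#' @param outdir Output directory (default `config$outdir`, or a fresh
#'   temporary directory).
#' @param quiet Suppress stage messages (default `FALSE`).
#' @return The run manifest (list of class `run_manifest`), invisibly:
#'   config snapshot, per-stage input/output file MD5 digests and record
#'   counts, seeds, package version, timestamps.
#' @export
run_all <- function(config, outdir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) outdir <- tempfile("dietscape_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stages <- list()
  t0 <- Sys.time()
  add_stage <- function(name, files, counts) {
    stages[[name]] <<- list(
      files = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))),
      counts = counts
    )
  }

  sc <- sim_config(
    n_zips = config$n_zips,
    participants_per_zip = config$participants_per_zip,
    entries_per_day_mean = config$entries_per_day_mean,
    active_days_mean = config$active_days_mean,
    noise_sd = config$noise_sd,
    seed = config$seed
  )

  say("simulate: ", config$n_zips, " zips, ",
      config$participants_per_zip, " participants/zip")
  tab <- gen_zip_table(sc)
  geo <- gen_geography(tab$covariates, sc)
  logs <- gen_food_logs(tab$outcomes, sc)
  f_cov <- write_stage_csv(tab$covariates, file.path(outdir, "sim_covariates.csv"))
  f_gt <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(tab$ground_truth, f_gt, digits = NA)
  f_tr <- write_stage_csv(geo$tracts, file.path(outdir, "tracts.csv"))
  f_cw <- write_stage_csv(geo$crosswalk, file.path(outdir, "crosswalk.csv"))
  f_bz <- write_stage_csv(geo$businesses, file.path(outdir, "businesses.csv"))
  f_lg <- write_stage_csv(logs$entries, file.path(outdir, "food_logs.csv"))
  f_pp <- write_stage_csv(logs$participants, file.path(outdir, "participants.csv"))
  add_stage("simulate", c(f_cov, f_gt, f_tr, f_cw, f_bz, f_lg, f_pp),
            list(zips = nrow(tab$covariates), entries = nrow(logs$entries),
                 participants = nrow(logs$participants)))

  say("classify + aggregate: ", nrow(logs$entries), " entries")
  agg <- aggregate_cohort(logs$entries, logs$participants,
                          min_days = config$min_days,
                          min_participants = config$min_participants)
  f_zo <- write_stage_csv(agg$zips, file.path(outdir, "zip_outcomes.csv"))
  add_stage("aggregate", f_zo,
            as.list(setNames(agg$attrition$n, agg$attrition$stage)))
  say("aggregate: ", nrow(agg$zips), " zips retained")

  say("environment: tract crosswalk + ", nrow(geo$businesses), " businesses")
  demo_cols <- c("zip", "income", "college_frac", "service_frac",
                 "frac_white", "frac_black", "frac_hispanic", "majority",
                 "ruca", "population", "centroid_lat", "centroid_lon")
  cov_hat <- build_zip_covariates(tab$covariates[, demo_cols],
                                  geo$tracts, geo$crosswalk, geo$businesses)
  f_cv <- write_stage_csv(cov_hat, file.path(outdir, "zip_covariates.csv"))
  add_stage("environment", f_cv, list(zips = nrow(cov_hat)))

  say("matching + estimation")
  all_results <- list()
  for (sg in config$subgroups) {
    for (f in config$factors) {
      res <- run_experiment(
        cov_hat, agg$zips, factor = f, subgroup = sg, split = config$split,
        reps = config$bootstrap_reps, seed = config$seed,
        balance_threshold = config$balance_threshold,
        caliper_start = config$caliper_start,
        caliper_step = config$caliper_step,
        ga_pop_size = config$ga_pop_size,
        ga_generations = config$ga_generations,
        weight_max = config$weight_max
      )
      key <- paste(f, sg, sep = ".")
      all_results[[key]] <- list(
        results = res$results,
        balance = res$balance[c("mean_smd", "median_smd", "max_abs_smd",
                                "balanced", "n_pairs", "n_dropped")],
        cut = res$cut
      )
      say("  ", key, ": ", res$balance$n_pairs, " pairs, max |SMD| ",
          format(res$balance$max_abs_smd, digits = 3))
    }
  }
  if (isTRUE(config$run_null)) {
    say("null-treatment check: ", config$null_factor)
    res <- null_experiment(cov_hat, agg$zips,
                           null_factor = config$null_factor,
                           reps = config$bootstrap_reps, seed = config$seed,
                           balance_threshold = config$balance_threshold,
                           caliper_start = config$caliper_start,
                           caliper_step = config$caliper_step,
                           ga_pop_size = config$ga_pop_size,
                           ga_generations = config$ga_generations,
                           weight_max = config$weight_max)
    all_results[[paste0("null.", config$null_factor)]] <- list(
      results = res$results,
      balance = res$balance[c("mean_smd", "median_smd", "max_abs_smd",
                              "balanced", "n_pairs", "n_dropped")],
      null_correlations = as.list(res$null_correlations)
    )
  }
  f_res <- file.path(outdir, "results.json")
  jsonlite::write_json(all_results, f_res, auto_unbox = TRUE, digits = NA)
  add_stage("estimate", f_res, list(experiments = length(all_results)))

  manifest <- structure(
    list(
      config = unclass(config),
      seed = config$seed,
      stages = stages,
      package_version = as.character(packageVersion("dietscape")),
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outdir = outdir
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    lapply(manifest, function(x) x)[names(manifest) != "class"],
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE
  )
  invisible(manifest)
}
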