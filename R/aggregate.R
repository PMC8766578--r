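#' Per-participant consumption rates over active days
#'
#' Aggregates labeled food-log entries in two stages that mirror the
#' study's clustering structure: first within participant-day (daily
#' counts of entries per category), then across each participant's active
#' days. An *active day* is a calendar date on which the participant
#' logged at least one entry of any kind; calendar gaps with no logging do
#' not enter the denominator.
#'
#' @param labeled_entries Data frame with columns `participant_id`,
#'   `log_date`, and logical `is_fv`, `is_fastfood`, `is_soda` (from
#'   [classify_entries()]).
#' @return Tibble with one row per participant: `participant_id`,
#'   `active_days`, `rate_fv`, `rate_fastfood`, `rate_soda` (mean labeled
#'   entries per active day).
#' @export
participant_rates <- function(labeled_entries) {
  needed <- c("participant_id", "log_date", "is_fv", "is_fastfood", "is_soda")
  if (!all(needed %in% names(labeled_entries))) {
    stop("labeled_entries must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(labeled_entries) == 0) {
    stop("no entries: rates undefined with zero active days", call. = FALSE)
  }
  daily <- labeled_entries %>%
    group_by(.data$participant_id, .data$log_date) %>%
    summarise(
      d_fv = sum(.data$is_fv),
      d_ff = sum(.data$is_fastfood),
      d_soda = sum(.data$is_soda),
      .groups = "drop"
    )
  daily %>%
    group_by(.data$participant_id) %>%
    summarise(
      active_days = n(),
      rate_fv = mean(.data$d_fv),
      rate_fastfood = mean(.data$d_ff),
      rate_soda = mean(.data$d_soda),
      .groups = "drop"
    )
}

#' Apply the minimum-usage participant filter
#'
#' Retains participants with at least `min_days` active days (boundary
#' inclusive), preserving input order.
#'
#' @param summaries Tibble from [participant_rates()] (optionally joined
#'   with participant metadata), with an `active_days` column.
#' @param min_days Minimum active days required (default 10).
#' @return The retained rows.
#' @export
filter_participants <- function(summaries, min_days = 10) {
  stopifnot(min_days >= 1)
  summaries[summaries$active_days >= min_days, , drop = FALSE]
}

#' Aggregate participant summaries to zip-code outcomes
#'
#' Takes the unweighted mean of each participant-level consumption rate
#' within a zip, and the fraction of BMI-reporting participants with
#' BMI strictly greater than 25 as the overweight/obesity outcome. Zips
#' with fewer than `min_participants` participants are dropped to protect
#' privacy and measure reliability. A zip with no BMI reporters keeps its
#' consumption outcomes but gets `overweight_fraction = NA` with a warning.
#'
#' @param summaries Participant summaries (already participant-filtered)
#'   with columns `participant_id`, `zip`, `rate_fv`, `rate_fastfood`,
#'   `rate_soda` and `bmi` (`NA` allowed).
#' @param min_participants Minimum participants per retained zip
#'   (default 30).
#' @return Tibble with one row per retained zip: `zip`, `n_participants`,
#'   `mean_fv`, `mean_fastfood`, `mean_soda`, `overweight_fraction`.
#' @export
zip_outcomes <- function(summaries, min_participants = 30) {
  needed <- c("participant_id", "zip", "rate_fv", "rate_fastfood",
              "rate_soda", "bmi")
  if (!all(needed %in% names(summaries))) {
    stop("summaries must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- summaries %>%
    group_by(zip = as.character(.data$zip)) %>%
    summarise(
      n_participants = n(),
      mean_fv = mean(.data$rate_fv),
      mean_fastfood = mean(.data$rate_fastfood),
      mean_soda = mean(.data$rate_soda),
      overweight_fraction = if (any(!is.na(.data$bmi))) {
        mean(.data$bmi[!is.na(.data$bmi)] > 25)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    filter(.data$n_participants >= min_participants)
  if (any(is.na(out$overweight_fraction))) {
    warning(sum(is.na(out$overweight_fraction)),
            " zip(s) have no BMI reporters; overweight_fraction set to NA",
            call. = FALSE)
  }
  out
}

#' Run the classify-and-aggregate stage end to end
#'
#' Convenience wrapper: classify raw entries, compute participant rates,
#' join participant zip/BMI metadata, apply the active-day and
#' participants-per-zip filters, and aggregate to zip outcomes.
#'
#' @param entries Raw food-log entries (see [read_food_logs()]).
#' @param participants Tibble with `participant_id`, `zip`, `bmi`.
#' @param rules Classification `ruleset`.
#' @param min_days,min_participants Inclusion filters (defaults 10, 30).
#' @return List with `participants` (filtered participant summaries) and
#'   `zips` (the [zip_outcomes()] table), plus an `attrition` count table.
#' @export
aggregate_cohort <- function(entries, participants, rules = load_rules(),
                             min_days = 10, min_participants = 30) {
  labeled <- classify_entries(entries, rules)
  rates <- participant_rates(labeled)
  merged <- dplyr::inner_join(rates,
                              dplyr::select(participants, "participant_id",
                                            "zip", "bmi"),
                              by = "participant_id")
  kept <- filter_participants(merged, min_days = min_days)
  zips <- zip_outcomes(kept, min_participants = min_participants)
  attrition <- tibble::tibble(
    stage = c("entries", "participants", "participants_min_days",
              "zips", "zips_min_participants"),
    n = c(nrow(entries), nrow(merged), nrow(kept),
          dplyr::n_distinct(kept$zip), nrow(zips))
  )
  list(participants = kept, zips = zips, attrition = attrition)
}
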