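# Entry-rendering vocabularies. Category templates produce strings the
# keyword classifiers must catch; distractors include near-miss strings
# ("Light Yogurt", "Zero Bar", "Apple Juice") that must NOT be caught.
log_vocab <- function() {
  list(
    fv = list(
      brand = c("", "", "Fresh Farms", "Natures Best", "Green Grocer"),
      descr = c("Banana, raw", "Apple, medium", "Spinach Salad",
                "Steamed Broccoli", "Baby Carrots", "Strawberries, 1 cup",
                "Kale, chopped", "Sweet Potato, baked", "Cucumber slices",
                "Mixed Greens Salad", "Bell Pepper, raw", "Blueberries")
    ),
    fastfood = list(
      brand = c("McDonald's", "Burger King", "Taco Bell", "KFC",
                "Wendy's", "Subway", "Pizza Hut", "Chipotle"),
      descr = c("Big Mac", "Fries, large", "Crunchwrap Supreme",
                "2 pc Fried Chicken", "Burrito Bowl", "Cheeseburger",
                "Pepperoni Slice", "Chicken Nuggets, 10 pc")
    ),
    soda = list(
      brand = c("Coca-Cola", "Pepsi", "Sprite", "Mountain Dew",
                "Dr Pepper", "Fanta"),
      descr = c("12oz can", "20oz bottle", "Fountain drink", "2 liter",
                "Classic, 12oz")
    ),
    distractor = list(
      brand = c("Campbells", "Kraft", "Quaker", "Wonder", "Chobani",
                "Tropicana", "Minute Maid", "Hersheys", "Yoplait",
                "Starbucks", "Barilla", "Tyson", "", "Naked"),
      descr = c("Chicken Noodle Soup", "Mac and Cheese", "Oatmeal, 1 cup",
                "Whole Wheat Bread, 2 slices", "Greek Yogurt, Plain",
                "Orange Juice, 8oz", "Apple Juice", "Zero Bar",
                "Light Yogurt", "Caffe Latte", "Spaghetti, cooked",
                "Grilled Chicken Breast", "Scrambled Eggs",
                "Green Machine Smoothie")
    )
  )
}

#' Generate participant food logs consistent with zip outcomes
#'
#' Simulates the raw inputs of the classify-and-aggregate stage so that
#' running the pipeline on them recovers each zip's outcome table.
#' Per participant: active days are drawn as `10 + NegBinomial` with the
#' configured mean (minimum usage of 10 days); per-category daily entry
#' counts are Poisson around a participant rate that is Gamma-distributed
#' around the zip mean (over-dispersion across participants); distractor
#' entries (soups, breads, juices, "Light"/"Zero" products, smoothies —
#' none of which may classify into a category) fill the total logging
#' volume to the configured entries-per-day mean. BMI is Normal around a
#' zip-specific mean chosen so the expected fraction above 25 equals the
#' zip's overweight fraction, with a small non-reporting rate.
#'
#' @param zip_outcomes Outcome table (from [gen_zip_outcomes()] or real
#'   data) with `zip`, `mean_fv`, `mean_fastfood`, `mean_soda`,
#'   `overweight_fraction`.
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed + 2`).
#' @return List: `entries` (food-log tibble with `participant_id`,
#'   `log_date`, `brand`, `description`, `serving_unit`, `n_servings`),
#'   `participants` (tibble `participant_id`, `zip`, `bmi`), and
#'   `realized` (per-participant `active_days` and the exact generated
#'   entry counts per category, for validating downstream recovery).
#' @export
gen_food_logs <- function(zip_outcomes, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  vocab <- log_vocab()
  n_zip <- nrow(zip_outcomes)
  ppz <- config$participants_per_zip
  n_part <- n_zip * ppz

  part <- tibble::tibble(
    participant_id = sprintf("p%06d", seq_len(n_part)),
    zip = rep(as.character(zip_outcomes$zip), each = ppz)
  )
  ow <- rep(zip_outcomes$overweight_fraction, each = ppz)
  bmi_mu <- 25 + config$bmi_sd * qnorm(pmin(0.999, pmax(0.001, ow)))
  part$bmi <- rnorm(n_part, bmi_mu, config$bmi_sd)
  part$bmi[runif(n_part) < config$bmi_missing_rate] <- NA_real_

  active_days <- 10 + rnbinom(n_part, size = 1.5,
                              mu = config$active_days_mean - 10)

  # participant rates: Gamma around the zip mean, shape 4
  zip_rates <- as.matrix(zip_outcomes[, c("mean_fv", "mean_fastfood",
                                          "mean_soda")])
  rate <- matrix(0, n_part, 3, dimnames = list(NULL, colnames(zip_rates)))
  for (j in 1:3) {
    mu <- rep(zip_rates[, j], each = ppz)
    rate[, j] <- rgamma(n_part, shape = 4, rate = 4 / pmax(mu, 1e-9))
  }
  distract_rate <- pmax(0.5, config$entries_per_day_mean - rowSums(rate))

  origin <- as.Date("2015-01-01")
  per_part <- lapply(seq_len(n_part), function(i) {
    nd <- active_days[i]
    dates <- origin + sort(sample.int(max(nd, 400), nd)) - 1
    counts <- cbind(
      fv = rpois(nd, rate[i, 1]),
      fastfood = rpois(nd, rate[i, 2]),
      soda = rpois(nd, rate[i, 3]),
      distractor = rpois(nd, distract_rate[i])
    )
    # an active day needs at least one entry of some kind
    empty <- rowSums(counts) == 0
    counts[empty, "distractor"] <- 1L
    cat_col <- rep(rep(colnames(counts), nd), as.vector(t(counts)))
    date_col <- rep(rep(dates, each = 4), as.vector(t(counts)))
    tibble::tibble(participant_id = part$participant_id[i],
                   log_date = date_col, category = cat_col)
  })
  entries <- dplyr::bind_rows(per_part)

  # realized per-participant counts: the exact answer the classify +
  # aggregate stage should reproduce from the rendered strings
  realized <- entries %>%
    dplyr::count(.data$participant_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (nm in c("n_fv", "n_fastfood", "n_soda", "n_distractor")) {
    if (!nm %in% names(realized)) realized[[nm]] <- 0L
  }
  realized$active_days <- active_days[match(realized$participant_id,
                                            part$participant_id)]
  realized <- realized[match(part$participant_id, realized$participant_id),
                       c("participant_id", "active_days", "n_fv",
                         "n_fastfood", "n_soda", "n_distractor")]

  n_e <- nrow(entries)
  brand <- character(n_e)
  descr <- character(n_e)
  for (cat in names(vocab)) {
    idx <- which(entries$category == cat)
    if (length(idx) == 0) next
    v <- vocab[[cat]]
    if (cat == "distractor") {
      # brand and description are paired so near-miss strings stay safe
      pick <- sample.int(length(v$brand), length(idx), replace = TRUE)
      brand[idx] <- v$brand[pick]
      descr[idx] <- v$descr[pick]
    } else {
      brand[idx] <- sample(v$brand, length(idx), replace = TRUE)
      descr[idx] <- sample(v$descr, length(idx), replace = TRUE)
    }
  }
  entries$brand <- brand
  entries$description <- descr
  entries$serving_unit <- sample(c("serving", "cup", "oz", "item"),
                                 n_e, replace = TRUE)
  entries$n_servings <- sample(c(0.5, 1, 1, 1, 1, 1.5, 2),
                               n_e, replace = TRUE)
  entries$category <- NULL
  list(entries = entries, participants = part, realized = realized)
}
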