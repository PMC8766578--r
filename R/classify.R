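#' Normalize free text for keyword matching
#'
#' Lower-cases, deletes punctuation characters (deletion, not replacement,
#' so hyphenated and unhyphenated brand spellings collide on purpose:
#' "Coca-Cola" and "CocaCola" both normalize to "cocacola"), collapses
#' whitespace runs to single spaces and trims the ends. Idempotent.
#'
#' @param x Character vector (may contain empty strings).
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_text("Diet Cherry Coke, 8oz")  # "diet cherry coke 8oz"
#' normalize_text("McDonald's")             # "mcdonalds"
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]+", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Regex alternation over normalized keywords; keywords are punctuation-free
# so no metacharacter escaping is needed.
kw_regex <- function(keywords, whole_token = FALSE) {
  alt <- paste(keywords, collapse = "|")
  if (whole_token) paste0("\\b(", alt, ")\\b") else paste0("(", alt, ")")
}

#' Classify food-log entries into diet categories
#'
#' Applies three independent binary keyword classifiers to each entry:
#' \describe{
#'   \item{fast food}{the normalized brand contains a chain name as a
#'     substring;}
#'   \item{soda}{the normalized brand contains a soda name as a substring
#'     AND the normalized description contains none of the excluder tokens
#'     ("diet", "lite", "light", "zero" at minimum), matched as whole
#'     tokens so e.g. "lite" does not fire inside "politely";}
#'   \item{fruit & vegetable}{the normalized brand or the normalized
#'     description (matched as separate fields, so a multi-word term can
#'     never span the field boundary) contains an F&V term and neither
#'     field contains an F&V excluder token (juice-type terms), so juices
#'     never count as fresh produce.}
#' }
#' The three labels are independent (multi-label); entries with all three
#' flags false are excluded from the analysis downstream.
#'
#' @param entries Data frame of food-log entries with character columns
#'   `brand` and `description` (other columns are passed through).
#' @param rules A `ruleset` from [load_rules()].
#' @return `entries` as a tibble with logical columns `is_fv`,
#'   `is_fastfood`, `is_soda` appended.
#' @export
#' @examples
#' rules <- load_rules()
#' logs <- tibble::tibble(
#'   brand = c("Coca Cola", "Pepsi", "McDonald's", ""),
#'   description = c("Diet Cherry Coke, 8oz", "Cherry, 12oz can",
#'                   "Big Mac", "Fresh Spinach Salad")
#' )
#' classify_entries(logs, rules)
classify_entries <- function(entries, rules = load_rules()) {
  validate_rules(rules)
  if (!all(c("brand", "description") %in% names(entries))) {
    stop("entries must have 'brand' and 'description' columns", call. = FALSE)
  }
  brand <- normalize_text(entries$brand)
  descr <- normalize_text(entries$description)

  is_fastfood <- stringr::str_detect(brand, kw_regex(rules$fastfood_chains))
  is_soda <- stringr::str_detect(brand, kw_regex(rules$soda_names)) &
    !stringr::str_detect(descr, kw_regex(rules$soda_excluders, whole_token = TRUE))
  # brand and description are matched as separate fields: concatenating
  # them would let a multi-word keyword span the field boundary
  # ("Taco Bell" + "Pepperoni Slice" must not contain "bell pepper")
  fv_inc <- kw_regex(rules$fv_keywords)
  fv_exc <- kw_regex(rules$fv_excluders, whole_token = TRUE)
  is_fv <- (stringr::str_detect(brand, fv_inc) |
              stringr::str_detect(descr, fv_inc)) &
    !(stringr::str_detect(brand, fv_exc) |
        stringr::str_detect(descr, fv_exc))

  dplyr::mutate(tibble::as_tibble(entries),
                is_fv = is_fv, is_fastfood = is_fastfood, is_soda = is_soda)
}

#' Estimate classifier precision from a manual audit sample
#'
#' Draws a seed-reproducible random sample (without replacement) from the
#' entries a classifier predicted positive, and returns the fraction of the
#' sampled entries that manual labels confirm: precision = true positives /
#' predicted positives within the audit sample. When fewer predicted
#' positives exist than the requested sample size, all of them are audited.
#'
#' @param predicted_positive Data frame of entries predicted positive.
#' @param manual_labels Logical vector aligned with `predicted_positive`
#'   rows: `TRUE` where the manual audit confirms the prediction.
#' @param sample_size Number of entries to audit (default 50).
#' @param seed Integer seed for the sampling.
#' @return A numeric precision in `[0, 1]` with attributes `n_sampled` and
#'   `sampled_rows` (the audited row indices).
#' @export
estimate_precision <- function(predicted_positive, manual_labels,
                               sample_size = 50, seed = 1L) {
  n <- nrow(predicted_positive)
  if (is.null(n) || n == 0) {
    stop("no predicted positives to audit", call. = FALSE)
  }
  if (length(manual_labels) != n) {
    stop("manual_labels must align with predicted_positive rows", call. = FALSE)
  }
  stopifnot(sample_size >= 1)
  set.seed(seed)
  idx <- if (n <= sample_size) seq_len(n) else sample.int(n, sample_size)
  precision <- mean(as.logical(manual_labels[idx]))
  structure(precision, n_sampled = length(idx), sampled_rows = idx)
}

#' Read a food-log CSV
#'
#' Expects the header `participant_id,log_date,brand,description,
#' serving_unit,n_servings` with ISO-8601 dates. Empty brand/description
#' fields are read as empty strings, never `NA`.
#'
#' @param path CSV file path.
#' @return Tibble of food-log entries with `log_date` parsed as `Date`.
#' @export
read_food_logs <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      log_date = readr::col_date(),
      brand = readr::col_character(),
      description = readr::col_character(),
      serving_unit = readr::col_character(),
      n_servings = readr::col_double()
    ),
    progress = FALSE
  )
  x$brand[is.na(x$brand)] <- ""
  x$description[is.na(x$description)] <- ""
  x$serving_unit[is.na(x$serving_unit)] <- ""
  if (any(x$n_servings < 0, na.rm = TRUE)) {
    stop("n_servings must be nonnegative", call. = FALSE)
  }
  x
}
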