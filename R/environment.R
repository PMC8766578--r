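#' Population-weighted census-tract-to-zip aggregation
#'
#' Aggregates a tract-level measure to zip level through a tract/zip
#' crosswalk, weighting each overlapping tract by its population:
#' `zip_value = sum(value * population) / sum(population)` over the zip's
#' tracts. For example, a zip overlapping a 2,500-person tract flagged as
#' a food desert and a 7,500-person tract that is not gets a food-desert
#' measure of 0.25.
#'
#' @param tracts Data frame with columns `tract_id`, `population`, and the
#'   value column named by `value_col`.
#' @param crosswalk Data frame with columns `zip`, `tract_id`; `(zip,
#'   tract_id)` pairs must be unique.
#' @param value_col Name of the tract value column to aggregate.
#' @return Tibble with columns `zip` and `value` (the weighted average);
#'   zips whose overlapping tracts have zero total population get `NA`
#'   with a warning.
#' @export
#' @examples
#' tracts <- tibble::tibble(tract_id = c("A", "B"),
#'                          population = c(2500, 7500),
#'                          food_desert = c(1, 0))
#' cw <- tibble::tibble(zip = "00001", tract_id = c("A", "B"))
#' tract_to_zip(tracts, cw, "food_desert")  # 0.25
tract_to_zip <- function(tracts, crosswalk, value_col) {
  stopifnot(all(c("tract_id", "population") %in% names(tracts)),
            all(c("zip", "tract_id") %in% names(crosswalk)),
            value_col %in% names(tracts))
  if (anyDuplicated(crosswalk[c("zip", "tract_id")])) {
    stop("crosswalk (zip, tract_id) pairs must be unique", call. = FALSE)
  }
  missing_tracts <- setdiff(crosswalk$tract_id, tracts$tract_id)
  if (length(missing_tracts) > 0) {
    stop("crosswalk references unknown tracts: ",
         paste(head(missing_tracts, 5), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(crosswalk, tracts, by = "tract_id")
  out <- joined %>%
    group_by(zip = as.character(.data$zip)) %>%
    summarise(
      value = if (sum(.data$population) > 0) {
        sum(.data[[value_col]] * .data$population) / sum(.data$population)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (any(is.na(out$value))) {
    warning(sum(is.na(out$value)),
            " zip(s) have zero overlapping population; value set to NA",
            call. = FALSE)
  }
  out
}

#' Grocery-access sign convention
#'
#' The tract tables store the fraction of population *more than* 0.5 miles
#' from the nearest grocery store; the analysis covariate is the fraction
#' *within* 0.5 miles, so that high access is the above-median (treated)
#' side. This helper flips the convention: `access = 1 - beyond`.
#'
#' @param beyond_half_mile_frac Fraction of population beyond 0.5 miles,
#'   in `[0, 1]` (`NA` passed through).
#' @return `1 - beyond_half_mile_frac`.
#' @export
grocery_access <- function(beyond_half_mile_frac) {
  bad <- !is.na(beyond_half_mile_frac) &
    (beyond_half_mile_frac < 0 | beyond_half_mile_frac > 1)
  if (any(bad)) {
    stop("beyond_half_mile_frac must lie in [0, 1]", call. = FALSE)
  }
  1 - beyond_half_mile_frac
}

#' Binary food-desert flag for a zip
#'
#' A zip counts as a food desert when its population-weighted food-desert
#' measure reaches the threshold, boundary inclusive (default 50%).
#'
#' @param food_desert_frac Weighted food-desert fraction in `[0, 1]`.
#' @param threshold Cut point (default 0.5).
#' @return Logical vector: `food_desert_frac >= threshold`.
#' @export
food_desert_flag <- function(food_desert_frac, threshold = 0.5) {
  stopifnot(all(food_desert_frac >= 0 & food_desert_frac <= 1, na.rm = TRUE))
  food_desert_frac >= threshold
}

# Great-circle distance in km (haversine, Earth radius 6371 km).
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Fast-food share of nearby restaurants
#'
#' For a zip centroid, selects the restaurants within `max_km`
#' (great-circle distance), keeps at most the `max_n` nearest (emulating a
#' capped nearest-neighbour business query), and returns the fraction of
#' the selected restaurants that are fast-food chains. Exact distance ties
#' are broken by stable input order.
#'
#' @param centroid Numeric `c(lat, lon)` in degrees.
#' @param businesses Data frame with columns `latitude`, `longitude`,
#'   `is_restaurant`, `is_fastfood_chain`.
#' @param max_n Maximum number of restaurants considered (default 1000).
#' @param max_km Search radius in km (default 40).
#' @return Fraction in `[0, 1]`, with attribute `n_considered`; `NA` (with
#'   a warning) when no restaurant lies within the radius.
#' @export
fastfood_access <- function(centroid, businesses, max_n = 1000, max_km = 40) {
  stopifnot(length(centroid) == 2,
            all(c("latitude", "longitude", "is_restaurant",
                  "is_fastfood_chain") %in% names(businesses)))
  if (any(businesses$is_fastfood_chain & !businesses$is_restaurant)) {
    stop("is_fastfood_chain implies is_restaurant", call. = FALSE)
  }
  rest <- businesses[businesses$is_restaurant, , drop = FALSE]
  if (nrow(rest) == 0) {
    warning("no restaurants supplied; fastfood_access is NA", call. = FALSE)
    return(structure(NA_real_, n_considered = 0L))
  }
  d <- haversine_km(centroid[1], centroid[2], rest$latitude, rest$longitude)
  in_radius <- which(d <= max_km)
  if (length(in_radius) == 0) {
    warning("no restaurants within ", max_km,
            " km of centroid; fastfood_access is NA", call. = FALSE)
    return(structure(NA_real_, n_considered = 0L))
  }
  sel <- in_radius[order(d[in_radius])] # order() is stable: ties keep input order
  sel <- head(sel, max_n)
  structure(mean(rest$is_fastfood_chain[sel]),
            n_considered = length(sel))
}

#' Assemble the zip-covariate table
#'
#' Combines demographic inputs with the derived food-environment measures:
#' population-weighted grocery access and food-desert fraction through the
#' tract crosswalk, and the fast-food share of nearby restaurants from
#' business point data.
#'
#' @param demographics Tibble keyed by `zip` with at least `income`,
#'   `college_frac`, `frac_white`, `frac_black`, `frac_hispanic`, `ruca`,
#'   `population`, `centroid_lat`, `centroid_lon`.
#' @param tracts,crosswalk Tract table (with `beyond_half_mile_frac` and
#'   `food_desert` columns) and zip/tract crosswalk for [tract_to_zip()].
#' @param businesses Business point table for [fastfood_access()].
#' @param max_n,max_km Passed to [fastfood_access()].
#' @return `demographics` with `grocery_access`, `food_desert_frac` and
#'   `fastfood_access` columns appended.
#' @export
build_zip_covariates <- function(demographics, tracts, crosswalk, businesses,
                                 max_n = 1000, max_km = 40) {
  stopifnot("zip" %in% names(demographics))
  demographics <- mutate(tibble::as_tibble(demographics),
                         zip = as.character(.data$zip))
  beyond <- rename(tract_to_zip(tracts, crosswalk, "beyond_half_mile_frac"),
                   beyond = "value")
  desert <- rename(tract_to_zip(tracts, crosswalk, "food_desert"),
                   food_desert_frac = "value")
  ff <- vapply(seq_len(nrow(demographics)), function(i) {
    suppressWarnings(as.numeric(fastfood_access(
      c(demographics$centroid_lat[i], demographics$centroid_lon[i]),
      businesses, max_n = max_n, max_km = max_km
    )))
  }, numeric(1))
  demographics %>%
    left_join(beyond, by = "zip") %>%
    left_join(desert, by = "zip") %>%
    mutate(
      grocery_access = grocery_access(.data$beyond),
      fastfood_access = ff
    ) %>%
    select(-"beyond")
}
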