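#' Generate synthetic tract, crosswalk and business-point tables
#'
#' Builds the geography inputs of the environment stage so that running
#' [build_zip_covariates()] on them reproduces each zip's configured
#' access values within sampling tolerance:
#' \itemize{
#'   \item 1-8 census tracts per zip with log-normal populations; each
#'     tract's beyond-half-mile fraction scatters narrowly around the
#'     zip's target (`1 - grocery_access`) and its food-desert flag is
#'     Bernoulli with the zip's target food-desert fraction;
#'   \item a crosswalk linking each tract to its zip;
#'   \item restaurants scattered uniformly within 10 km of each centroid
#'     (a spatial Poisson process), flagged fast-food with the zip's
#'     target probability, plus non-restaurant businesses.
#' }
#'
#' @param covariates Zip-covariate table from [gen_zip_covariates()]
#'   (uses `zip`, `grocery_access`, `food_desert_frac`,
#'   `fastfood_access`, `centroid_lat`, `centroid_lon`, `population`).
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed + 3`).
#' @return List: `tracts` (tibble `tract_id`, `population`,
#'   `beyond_half_mile_frac`, `food_desert`), `crosswalk` (`zip`,
#'   `tract_id`), `businesses` (`latitude`, `longitude`, `is_restaurant`,
#'   `is_fastfood_chain`), `centroids` (`zip`, `centroid_lat`,
#'   `centroid_lon`).
#' @export
gen_geography <- function(covariates, config, seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- nrow(covariates)

  n_tracts <- sample.int(8, n, replace = TRUE)
  zip_of_tract <- rep(as.character(covariates$zip), n_tracts)
  n_t <- length(zip_of_tract)
  target_beyond <- rep(1 - covariates$grocery_access, n_tracts)
  target_desert <- rep(covariates$food_desert_frac, n_tracts)

  tracts <- tibble::tibble(
    tract_id = sprintf("t%06d", seq_len(n_t)),
    population = round(exp(log(4000) + rnorm(n_t, 0, 0.5))),
    beyond_half_mile_frac = pmin(1, pmax(0, target_beyond +
                                           runif(n_t, -0.05, 0.05))),
    food_desert = rbinom(n_t, 1, target_desert)
  )
  crosswalk <- tibble::tibble(zip = zip_of_tract, tract_id = tracts$tract_id)

  n_rest <- rpois(n, config$restaurants_per_zip)
  n_other <- rpois(n, config$other_businesses_per_zip)
  n_biz <- n_rest + n_other
  zip_of_biz <- rep(seq_len(n), n_biz)
  n_b <- length(zip_of_biz)
  # uniform on a 10 km disc around the centroid
  r_km <- 10 * sqrt(runif(n_b))
  theta <- runif(n_b, 0, 2 * pi)
  lat0 <- covariates$centroid_lat[zip_of_biz]
  lon0 <- covariates$centroid_lon[zip_of_biz]
  lat <- lat0 + (r_km * sin(theta)) / 111
  lon <- lon0 + (r_km * cos(theta)) / (111 * cos(lat0 * pi / 180))
  is_rest <- unlist(lapply(seq_len(n), function(i) {
    c(rep(TRUE, n_rest[i]), rep(FALSE, n_other[i]))
  }))
  p_chain <- covariates$fastfood_access[zip_of_biz]
  businesses <- tibble::tibble(
    latitude = lat,
    longitude = lon,
    is_restaurant = is_rest,
    is_fastfood_chain = is_rest & (runif(n_b) < p_chain)
  )
  list(
    tracts = tracts,
    crosswalk = crosswalk,
    businesses = businesses,
    centroids = tibble::tibble(zip = as.character(covariates$zip),
                               centroid_lat = covariates$centroid_lat,
                               centroid_lon = covariates$centroid_lon)
  )
}
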