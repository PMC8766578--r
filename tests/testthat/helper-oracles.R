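# Brute-force oracles, written independently of the package internals:
# plain R loops, no calls into the matching kernel.

# Haversine distance in km, explicit formula (Earth radius 6371 km).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Nearest-control match with replacement by explicit loops.
oracle_match <- function(xt, xc, w, caliper = Inf) {
  nt <- nrow(xt)
  out <- integer(nt)
  for (i in seq_len(nt)) {
    best <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(xc))) {
      diff <- xt[i, ] - xc[j, ]
      if (any(abs(diff) > caliper)) next
      d <- sum(w * diff^2)
      if (d < best) {
        best <- d
        best_j <- j
      }
    }
    out[i] <- best_j
  }
  out
}

# Mean absolute SMD (control-group post-matching SD) of a match.
oracle_fitness <- function(xt, xc, match_idx) {
  keep <- !is.na(match_idx)
  smds <- vapply(seq_len(ncol(xt)), function(m) {
    tv <- xt[keep, m]
    cv <- xc[match_idx[keep], m]
    s <- sd(cv)
    if (s == 0) {
      if (mean(tv) == mean(cv)) 0 else Inf
    } else {
      (mean(tv) - mean(cv)) / s
    }
  }, numeric(1))
  mean(abs(smds))
}

# Small standardized covariate deck for matching oracles.
make_deck <- function(n_treated, n_control, k = 3, seed = 1) {
  set.seed(seed)
  n <- n_treated + n_control
  X <- matrix(rnorm(n * k), nrow = n)
  Z <- scale(X)
  list(
    zips = tibble::tibble(
      zip = sprintf("%05d", seq_len(n)),
      v1 = X[, 1],
      v2 = if (k >= 2) X[, 2] else NULL,
      v3 = if (k >= 3) X[, 3] else NULL
    ),
    treated = c(rep(TRUE, n_treated), rep(FALSE, n_control)),
    Z = Z
  )
}

# Hand-built matched_pairs object for inference tests.
fake_pairs <- function(treated_zip, control_zip, distance = 0) {
  structure(
    list(pairs = tibble::tibble(treated_zip = as.character(treated_zip),
                                control_zip = as.character(control_zip),
                                distance = distance),
         dropped_treated = character(0),
         weights = c(x = 1), caliper_used = NA_real_,
         fitness = 0, smd = c(x = 0),
         config = NULL),
    class = "matched_pairs"
  )
}

# Labeled-entry fixture: counts per participant/date/category.
labeled_fixture <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      participant_id = r$id,
      log_date = as.Date(r$date),
      is_fv = rep(c(TRUE, FALSE), c(r$fv, r$n - r$fv)),
      is_fastfood = rep(c(TRUE, FALSE), c(r$ff, r$n - r$ff)),
      is_soda = rep(c(TRUE, FALSE), c(r$soda, r$n - r$soda))
    )
  }))
}
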