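# 03: rebuild the food-environment covariates from the tract crosswalk
# and the business registry, and check how well the stage recovers the
# generator's latent environment.
source("analysis/00_settings.R")

cov_true <- read_csv(file.path(SCRATCH, "covariates.csv"),
                     show_col_types = FALSE,
                     col_types = cols(zip = col_character()))
tracts <- read_csv(file.path(SCRATCH, "tracts.csv"), show_col_types = FALSE)
crosswalk <- read_csv(file.path(SCRATCH, "crosswalk.csv"),
                      show_col_types = FALSE,
                      col_types = cols(zip = col_character()))
businesses <- read_csv(file.path(SCRATCH, "businesses.csv"),
                       show_col_types = FALSE)

demo <- cov_true[, c("zip", "income", "college_frac", "service_frac",
                     "frac_white", "frac_black", "frac_hispanic",
                     "majority", "ruca", "population",
                     "centroid_lat", "centroid_lon")]
cov <- build_zip_covariates(demo, tracts, crosswalk, businesses)
write_csv(cov, file.path(SCRATCH, "zip_covariates.csv"))

recovery <- data.frame(
  covariate = c("grocery_access", "fastfood_access", "food_desert_frac"),
  mean_abs_error = c(
    mean(abs(cov$grocery_access - cov_true$grocery_access)),
    mean(abs(cov$fastfood_access - cov_true$fastfood_access)),
    mean(abs(cov$food_desert_frac - cov_true$food_desert_frac))
  )
)
write_csv(recovery, file.path(RESULTS, "environment_recovery.csv"))
print(recovery, row.names = FALSE)
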