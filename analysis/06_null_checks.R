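# 06: negative control. The service-employment fraction is generated
# independently of diet, so matching on all four study factors and
# "treating" on it should show no effect; its correlations with the study
# factors should also be near zero.
source("analysis/00_settings.R")

cov <- read_csv(file.path(SCRATCH, "zip_covariates.csv"),
                show_col_types = FALSE,
                col_types = cols(zip = col_character()))
out <- read_csv(file.path(SCRATCH, "zip_outcomes.csv"),
                show_col_types = FALSE,
                col_types = cols(zip = col_character()))

res <- null_experiment(cov, out, "service_frac", seed = STUDY_SEED)
nulls <- res$results
nulls$covers_zero <- nulls$ci_low_pct <= 0 & nulls$ci_high_pct >= 0
write_csv(nulls, file.path(RESULTS, "null_estimates.csv"))
write_csv(data.frame(factor = names(res$null_correlations),
                     r = unname(res$null_correlations)),
          file.path(RESULTS, "null_correlations.csv"))
print(as.data.frame(nulls), row.names = FALSE, digits = 3)
print(res$null_correlations, digits = 2)
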