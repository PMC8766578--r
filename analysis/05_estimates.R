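# 05: matched-pair treatment-effect estimates. For each study factor and
# each diet outcome: the relative difference between matched treated and
# control zips, with a 1,000-replicate matched-pair bootstrap interval
# and a paired t-test cross-check; then the same for racial/ethnic
# majority subgroups.
source("analysis/00_settings.R")

cov <- read_csv(file.path(SCRATCH, "zip_covariates.csv"),
                show_col_types = FALSE,
                col_types = cols(zip = col_character()))
out <- read_csv(file.path(SCRATCH, "zip_outcomes.csv"),
                show_col_types = FALSE,
                col_types = cols(zip = col_character()))

all_res <- list()
for (f in study_factors()) {
  for (sg in c("all", "white_majority", "hispanic_majority",
               "black_majority")) {
    res <- tryCatch(
      run_experiment(cov, out, f, subgroup = sg, seed = STUDY_SEED),
      error = function(e) {
        message(f, " / ", sg, ": skipped (", conditionMessage(e), ")")
        NULL
      }
    )
    if (!is.null(res)) all_res[[paste(f, sg, sep = ".")]] <- res$results
  }
}
estimates <- do.call(rbind, all_res)
write_csv(estimates, file.path(RESULTS, "estimates.csv"))
print(as.data.frame(estimates[estimates$subgroup == "all", ]),
      row.names = FALSE, digits = 3)
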