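# 01: draw the synthetic cohort — zip covariates, true outcomes, the
# tract/business geography, and raw participant food logs.
source("analysis/00_settings.R")

tab <- gen_zip_table(STUDY)
geo <- gen_geography(tab$covariates, STUDY)
logs <- gen_food_logs(tab$outcomes, STUDY)

write_csv(tab$covariates, file.path(SCRATCH, "covariates.csv"))
write_csv(tab$outcomes, file.path(SCRATCH, "outcomes_true.csv"))
write_csv(tab$ground_truth, file.path(RESULTS, "ground_truth.csv"))
write_csv(geo$tracts, file.path(SCRATCH, "tracts.csv"))
write_csv(geo$crosswalk, file.path(SCRATCH, "crosswalk.csv"))
write_csv(geo$businesses, file.path(SCRATCH, "businesses.csv"))
write_csv(logs$entries, file.path(SCRATCH, "food_logs.csv"))
write_csv(logs$participants, file.path(SCRATCH, "participants.csv"))

summary_tab <- data.frame(
  quantity = c("zips", "participants", "log entries",
               "median income", "median college fraction",
               "median grocery access", "median fast-food access"),
  value = c(nrow(tab$covariates), nrow(logs$participants),
            nrow(logs$entries),
            round(median(tab$covariates$income)),
            round(median(tab$covariates$college_frac), 3),
            round(median(tab$covariates$grocery_access), 3),
            round(median(tab$covariates$fastfood_access), 3))
)
write_csv(summary_tab, file.path(RESULTS, "cohort_summary.csv"))
print(summary_tab, row.names = FALSE)
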