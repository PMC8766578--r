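# 02: classify the raw food-log strings and aggregate them to
# participant- and zip-level diet outcomes, applying the usage filters
# (>= 10 active days per participant, >= 30 participants per zip).
source("analysis/00_settings.R")

entries <- read_food_logs(file.path(SCRATCH, "food_logs.csv"))
participants <- read_csv(file.path(SCRATCH, "participants.csv"),
                         show_col_types = FALSE,
                         col_types = cols(zip = col_character()))

agg <- aggregate_cohort(entries, participants)

write_csv(agg$zips, file.path(SCRATCH, "zip_outcomes.csv"))
write_csv(agg$attrition, file.path(RESULTS, "attrition.csv"))
print(agg$attrition, n = Inf)
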