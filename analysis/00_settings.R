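# Shared settings for the analysis scripts. Large intermediates go to
# scratch/ (disposable); small summary tables go to results/.
suppressPackageStartupMessages({
  library(dietscape)
  library(readr)
})

SCRATCH <- "scratch/analysis"
RESULTS <- "results"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

# Study-scale-inspired synthetic cohort, sized to run in minutes on a
# laptop. All generator defaults (entry volume, usage duration, cut
# points, effect sizes) are the package defaults.
STUDY_SEED <- 20151001
STUDY <- sim_config(
  n_zips = 400,
  participants_per_zip = 32,
  active_days_mean = 20,
  seed = STUDY_SEED
)
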