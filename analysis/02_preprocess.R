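#!/usr/bin/env Rscript
# Step 2 -- participant screening and trial filtering.
#
# Applies the exclusion rules: participants whose mean correct-trial RT lies
# more than 2.5 sample SDs from the sample mean, or whose accuracy is below
# 95%, are dropped; then incorrect trials are discarded and, per participant,
# trials whose log RT deviates more than 3 SD from that participant's mean
# (single pass). The analysis response 1/RT (1/s) is appended.

suppressPackageStartupMessages(library(prepdyn))

trials <- read_trials("results/trials.csv")
pp <- preprocess(trials)

readr::write_csv(pp$trials, "results/trials_clean.csv") # includes inv_rt
jsonlite::write_json(
  list(excluded_participants = pp$screen$excluded,
       per_participant = pp$report),
  "results/filter_report.json", auto_unbox = TRUE, digits = NA)

cat(nrow(pp$screen$excluded), "participant(s) excluded;",
    length(pp$screen$included), "retained\n")
frac <- pp$report$fraction_discarded
cat(sprintf("log-RT outliers among correct trials: M = %.2f%%, SD = %.2f%%\n",
            100 * mean(frac), 100 * sd(frac)))
cat(sprintf("%d of %d trials retained\n", nrow(pp$trials), nrow(trials)))
cat("Wrote results/trials_clean.csv and results/filter_report.json\n")
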