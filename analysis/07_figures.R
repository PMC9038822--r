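#!/usr/bin/env Rscript
# Step 7 -- figures of record.
#
# RT-FP curves per S1 type and phase with 95% Cousineau-Morey within-subject
# intervals, and the four delta-beta time courses with block breaks and
# significant clusters marked. Both are drawn from the CSV/JSON intermediates
# written by the earlier steps, so every plotted number is inspectable.

suppressPackageStartupMessages(library(prepdyn))

trials <- readr::read_csv("results/trials_clean.csv", show_col_types = FALSE)
tc <- readr::read_csv("results/timecourse.csv", show_col_types = FALSE)
tc$coefficient <- factor(tc$coefficient,
                         levels = c("Intercept", "FP", "S1type", "FPxS1type"))
clusters <- jsonlite::read_json("results/clusters.json", simplifyVector = TRUE)
clusters <- lapply(clusters[c("Intercept", "FP", "S1type", "FPxS1type")],
                   tibble::as_tibble)

dir.create("results", showWarnings = FALSE)
ggplot2::ggsave("results/fig_rt_fp.png", plot_rt_fp(trials),
                width = 7, height = 4, dpi = 150)
ggplot2::ggsave("results/fig_timecourse.png",
                plot_timecourse(tc, clusters = clusters),
                width = 7, height = 9, dpi = 150)
cat("Wrote results/fig_rt_fp.png and results/fig_timecourse.png\n")
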