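#!/usr/bin/env Rscript
# Tidy tables for plotting: per-movie response proportions with fitted
# psychometric curves per experiment x prevalence condition, and
# per-quartile miss-rate means with percentile-bootstrap 95% confidence
# intervals over participants.

suppressPackageStartupMessages(library(roadlpe))

merged <- read_merged("results/merged.csv")
bundle <- list(merged = merged,
               miss_cells = miss_rates(merged, by_quartile = TRUE),
               config = pipeline_config(
                 input = list(trials_path = "results/data/trials.csv",
                              ratings_path = "results/data/ratings.csv"),
                 bootstrap = list(B = 10000, seed = 3)))

figs <- make_figure_tables(bundle, "results")
cat("psychometric figure table:", nrow(figs$psychometric), "rows",
    "(movie points + curve samples per experiment x condition)\n")
cat("quartile miss-rate figure table:\n")
print(figs$quartile_miss, row.names = FALSE, digits = 3)
cat("wrote results/fig_psychometric.csv, results/fig_quartile_miss.csv\n")
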