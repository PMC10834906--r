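#!/usr/bin/env Rscript
# Simulate the five-experiment hazard-detection study.
#
# One shared corpus of 1376 road movies (432 hazard-present, 944
# hazard-absent) is rated by a 48-driver panel; each experiment then runs
# a two-session prevalence manipulation (50%/4%, or 10%/1% for the
# lower-prevalence experiment) with a feedback-matched synthetic
# observer. Writes the trial and rating files the ingest step reads.

suppressPackageStartupMessages(library(roadlpe))

seed <- 1
out_dir <- "results/data"

study <- simulate_study(experiments = 1:5, seed = seed,
                        n_present = 432, n_absent = 944, n_raters = 48)
paths <- write_simulated_study(
  study, out_dir,
  params = list(seed = seed, experiments = 1:5, n_present = 432,
                n_absent = 944, n_raters = 48,
                observer = "feedback-matched presets"))

cat("simulated", nrow(study$trials), "trials for",
    length(unique(study$trials$participant_id)), "participants across",
    length(study$designs), "experiments\n")
cat("rating panel:", nrow(study$ratings), "records (",
    length(unique(study$ratings$movie_id)), "movies x",
    length(unique(study$ratings$rater_id)), "raters )\n")
cat("wrote:", paste(paths, collapse = ", "), "\n")
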