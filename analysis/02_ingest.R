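#!/usr/bin/env Rscript
# Ingest and merge: read the trial and rating files, compute per-movie
# median hazardousness, join trials to medians, and label hazard-present
# movies with hazardousness quartiles (Q1 least .. Q4 most hazardous).

suppressPackageStartupMessages(library(roadlpe))

trials <- read_trials("results/data/trials.csv")
ratings <- read_ratings("results/data/ratings.csv")
cat("trials read:", nrow(trials), "rows (",
    load_report(trials)$n_dropped, "dropped )\n")
cat("ratings read:", nrow(ratings), "rows (",
    load_report(ratings)$n_dropped, "dropped )\n")

medians <- compute_median_ratings(ratings)
merged <- merge_trials_ratings(trials, medians)
cat("merged:", nrow(merged), "trial rows;",
    load_report(merged)$n_dropped, "dropped in the join\n")
cat("quartile sizes (hazard-present movies):\n")
hz <- unique(merged[merged$hazard_present, c("movie_id", "quartile")])
print(table(hz$quartile))

write_merged(merged, "results/merged.csv")
jsonlite::write_json(
  list(trials = load_report(trials)[c("n_rows", "n_kept", "n_dropped")],
       ratings = load_report(ratings)[c("n_rows", "n_kept", "n_dropped")],
       merge = load_report(merged)[c("n_rows", "n_kept", "n_dropped")]),
  "results/load_report.json", auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/merged.csv and results/load_report.json\n")
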