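#!/usr/bin/env Rscript
# LPE statistics and within-participant permutation tests.
#
# Per experiment: the threshold-shift LPE (low minus high prevalence
# 50% threshold) with a condition-swap permutation p-value; per
# hazardousness quartile, the miss-rate LPE with its own condition-swap
# p-value; and Q4-vs-Q1..Q3 contrasts tested by shuffling quartile
# labels within participants. Bonferroni control over the 20-test
# quartile family. Emits a Table-1-shaped summary.

suppressPackageStartupMessages(library(roadlpe))

B <- 1000
seed <- 2

merged <- read_merged("results/merged.csv")
experiments <- unique(merged$experiment_id)
cells <- miss_rates(merged, by_quartile = TRUE)

table1 <- NULL
contrasts <- NULL
for (i in seq_along(experiments)) {
  eid <- experiments[i]
  sub <- merged[merged$experiment_id == eid, , drop = FALSE]
  th <- threshold_lpe(sub, eid, method = "logistic")
  th_p <- permute_condition_swap(pair_condition_trials(sub),
                                 stat_threshold_diff, B = B,
                                 seed = seed + 10 * i)
  row <- data.frame(experiment_id = eid, threshold_lpe = th$value,
                    threshold_p = th_p$p_value)
  cells_e <- cells[cells$experiment_id == eid, ]
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    qp <- permute_condition_swap(pair_miss_cells(cells_e, q),
                                 stat_mean_diff, B = B,
                                 seed = seed + 10 * i + match(q, paste0("Q", 1:4)))
    row[[paste0("lpe_", q)]] <- qp$observed
    row[[paste0("p_", q)]] <- qp$p_value
  }
  table1 <- rbind(table1, row)
  for (q in c("Q1", "Q2", "Q3")) {
    cp <- permute_quartile_shuffle(sub, focal_quartile = "Q4",
                                   contrast = q, B = B,
                                   seed = seed + 100 * i + match(q, paste0("Q", 1:3)))
    contrasts <- rbind(contrasts, data.frame(
      experiment_id = eid, contrast = paste0("Q4_minus_", q),
      diff = cp$observed, p = cp$p_value))
  }
}

cat("Table-1-shaped summary (threshold LPE and per-quartile miss-rate LPE,\n")
cat("permutation p-values, B =", B, "):\n")
print(table1, row.names = FALSE, digits = 3)

qp_family <- unlist(lapply(seq_len(nrow(table1)), function(i)
  setNames(as.numeric(table1[i, paste0("p_", c("Q1", "Q2", "Q3", "Q4"))]),
           paste0(table1$experiment_id[i], "_", c("Q1", "Q2", "Q3", "Q4")))))
bq <- bonferroni(qp_family, alpha = 0.05)
cat(sprintf("\nquartile family: %d tests, Bonferroni critical alpha %.4f, %d significant\n",
            nrow(bq), attr(bq, "critical_alpha"), sum(bq$significant)))

prop <- proportional_lpe(cells)
cat("\nproportional LPE (low/high miss-rate ratio) by experiment x quartile:\n")
print(prop[c("experiment_id", "quartile", "ratio")], row.names = FALSE,
      digits = 3)

utils::write.csv(table1, "results/table1.csv", row.names = FALSE)
utils::write.csv(contrasts, "results/quartile_contrasts.csv",
                 row.names = FALSE)
utils::write.csv(bq, "results/bonferroni_quartile.csv", row.names = FALSE)
utils::write.csv(prop, "results/proportional_lpe.csv", row.names = FALSE)
cat("\nwrote results/table1.csv, results/quartile_contrasts.csv,",
    "results/bonferroni_quartile.csv, results/proportional_lpe.csv\n")
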