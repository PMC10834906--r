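# Quartiles, miss rates, LPE statistics, permutation tests, Bonferroni.

test_that("distinct medians split evenly into quartiles, Q1 least hazardous", {
  med8 <- data.frame(movie_id = paste0("m", 1:8),
                     median_rating = seq(0.1, 0.8, by = 0.1))
  q8 <- assign_quartiles(med8)
  expect_equal(unname(table(q8$map$quartile)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_equal(q8$map$quartile[q8$map$movie_id == "m1"], "Q1")
  expect_equal(q8$map$quartile[q8$map$movie_id == "m8"], "Q4")
  expect_error(assign_quartiles(med8[1:3, ]), ">= 4")
})

test_that("ties at cut points go to the lower quartile, matching a rule-following oracle", {
  set.seed(9)
  vals <- sample(round(runif(60), 1))  # heavy ties on a coarse grid
  med <- data.frame(movie_id = paste0("m", seq_along(vals)),
                    median_rating = vals)
  q <- assign_quartiles(med)
  cuts <- q$cut_points
  oracle <- vapply(vals, function(v)
    paste0("Q", 1 + sum(v > cuts)), character(1))
  expect_equal(q$map$quartile, oracle)
})

test_that("miss rates are simple arithmetic with undefined (never 0) empty cells", {
  tab <- data.frame(
    participant_id = "p1", experiment_id = "e1",
    prevalence_condition = rep(c("high", "low"), c(5, 2)),
    session_order = "first",
    movie_id = paste0("m", 1:7), hazard_present = TRUE,
    response_yes = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    median_rating = 0.5, quartile = "Q2", stringsAsFactors = FALSE)
  cells <- miss_rates(tab, by_quartile = TRUE)
  expect_equal(cells$miss_rate[cells$prevalence_condition == "high" &
                                 cells$quartile == "Q2"], 2 / 5)
  expect_equal(cells$miss_rate[cells$prevalence_condition == "low" &
                                 cells$quartile == "Q2"], 0)
  # quartiles the participant never saw are undefined, not zero
  empty <- cells[cells$quartile == "Q1", ]
  expect_true(all(is.na(empty$miss_rate)))
  expect_true(all(empty$n_hazard_trials == 0))
})

test_that("per-quartile hazard-trial counts match an independent tally", {
  st <- tiny_study(seed = 17, n_participants = 4)
  cells <- miss_rates(st$merged, by_quartile = TRUE)
  hz <- st$merged[st$merged$hazard_present, ]
  for (i in sample(nrow(cells), 20)) {
    g <- cells[i, ]
    sel <- hz$participant_id == g$participant_id &
      hz$prevalence_condition == g$prevalence_condition &
      hz$quartile == g$quartile
    expect_equal(g$n_hazard_trials, sum(sel))
    expect_equal(g$n_misses, sum(sel & !hz$response_yes))
  }
  # low-prevalence sessions contain exactly the designed 8 hazard trials,
  # split across quartiles
  low <- cells[cells$prevalence_condition == "low", ]
  per_part <- tapply(low$n_hazard_trials, low$participant_id, sum)
  expect_true(all(per_part == round(0.1 * 80)))
})

test_that("miss-rate LPE: constant difference, null, antisymmetry, exclusions", {
  cells <- expand.grid(participant_id = paste0("p", 1:5),
                       prevalence_condition = c("high", "low"),
                       stringsAsFactors = FALSE)
  cells$experiment_id <- "e1"; cells$quartile <- "overall"
  cells$n_hazard_trials <- 10
  cells$miss_rate <- ifelse(cells$prevalence_condition == "low", 0.4, 0.1)
  cells$n_misses <- cells$miss_rate * 10
  expect_equal(lpe_miss(cells)$lpe, 0.3)

  cells$miss_rate <- 0.2
  expect_equal(lpe_miss(cells)$lpe, 0)

  cells$miss_rate <- ifelse(cells$prevalence_condition == "low", 0.4, 0.1)
  swapped <- cells
  swapped$prevalence_condition <- ifelse(cells$prevalence_condition ==
                                           "high", "low", "high")
  expect_equal(lpe_miss(swapped)$lpe, -lpe_miss(cells)$lpe)

  cells$miss_rate[cells$participant_id == "p5" &
                    cells$prevalence_condition == "low"] <- NA
  out <- lpe_miss(cells)
  expect_equal(out$n_used, 4)
  expect_equal(out$n_excluded, 1)
})

test_that("proportional LPE: arithmetic, null ratio, undefined denominator", {
  cells <- expand.grid(participant_id = paste0("p", 1:4),
                       prevalence_condition = c("high", "low"),
                       stringsAsFactors = FALSE)
  cells$experiment_id <- "e1"; cells$quartile <- "Q1"
  cells$n_hazard_trials <- 10
  cells$miss_rate <- ifelse(cells$prevalence_condition == "low", 0.3, 0.1)
  cells$n_misses <- cells$miss_rate * 10
  expect_equal(proportional_lpe(cells)$ratio, 3)

  cells$miss_rate <- 0.25
  expect_equal(proportional_lpe(cells)$ratio, 1)

  cells$miss_rate[cells$prevalence_condition == "high"] <- 0
  out <- proportional_lpe(cells)
  expect_true(out$undefined)
  expect_true(is.na(out$ratio))
})

test_that("shifted generator yields ratios above 1 in every quartile, near the analytic ratio", {
  st <- tiny_study(seed = 23, n_participants = 16, n_present = 120,
                   n_absent = 240, n_trials_high = 120, n_trials_low = 120,
                   prevalence_low = 0.25, lapse_rate = 0,
                   motor_error_rate = 0)
  prop <- proportional_lpe(miss_rates(st$merged, by_quartile = TRUE))
  qmap <- assign_quartiles(
    st$medians[st$medians$movie_id %in%
                 st$stimuli$movie_id[st$stimuli$hazard_present], ])
  med_q <- merge(st$medians, qmap$map)
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    r <- med_q$median_rating[med_q$quartile == q]
    analytic <- mean(1 - p_yes_analytic(st$observer, r, "low")) /
      mean(1 - p_yes_analytic(st$observer, r, "high"))
    got <- prop$ratio[prop$quartile == q]
    expect_gt(got, 1)
    expect_lt(abs(got - analytic) / analytic, 0.5)
  }
})

test_that("condition-swap test returns p = 1 when the statistic cannot move", {
  pairs <- lapply(1:5, function(i) list(high = 0.3, low = 0.3))
  names(pairs) <- paste0("p", 1:5)
  res <- permute_condition_swap(pairs, stat_mean_diff, B = 99, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed, 0)
})

test_that("Monte-Carlo condition-swap p matches exhaustive enumeration", {
  set.seed(5)
  pairs <- lapply(1:4, function(i)
    list(high = runif(1, 0, 0.3), low = runif(1, 0.1, 0.6)))
  names(pairs) <- paste0("p", 1:4)
  exact <- exact_swap_p(pairs, stat_mean_diff)
  mc <- permute_condition_swap(pairs, stat_mean_diff, B = 5000, seed = 2)
  expect_lt(abs(mc$p_value - exact), 0.02)
})

test_that("participants missing a condition are excluded with a warning", {
  pairs <- list(p1 = list(high = 0.1, low = 0.5),
                p2 = list(high = 0.2, low = NULL))
  expect_warning(res <- permute_condition_swap(pairs, stat_mean_diff,
                                               B = 49, seed = 1),
                 "missing a condition")
  expect_equal(res$n_units, 1)
  expect_error(
    suppressWarnings(permute_condition_swap(
      list(p1 = list(high = 1, low = NULL)), stat_mean_diff, B = 9)),
    "no participant")
})

test_that("quartile shuffle matches exhaustive label-permutation enumeration", {
  # single participant, 4 movies in 2 quartiles, both conditions per movie
  tab <- data.frame(
    participant_id = "p1", experiment_id = "e1",
    prevalence_condition = rep(c("high", "low"), each = 4),
    session_order = "first",
    movie_id = rep(paste0("m", 1:4), 2), hazard_present = TRUE,
    response_yes = c(TRUE, TRUE, FALSE, TRUE,   # high: misses on m3
                     FALSE, FALSE, TRUE, FALSE),  # low: misses m1 m2 m4
    median_rating = c(0.2, 0.3, 0.7, 0.8),
    quartile = rep(c("Q1", "Q1", "Q4", "Q4"), 2),
    stringsAsFactors = FALSE)
  res <- permute_quartile_shuffle(tab, focal_quartile = "Q4", B = 4000,
                                  seed = 3)
  # exhaustive oracle over all 4! orderings of the label vector
  labs <- c("Q1", "Q1", "Q4", "Q4")
  miss_high <- c(0, 0, 1, 0); miss_low <- c(1, 1, 0, 1)
  stat_for <- function(lab) {
    sel <- lab == "Q4"
    sum(miss_low[sel]) / sum(sel) - sum(miss_high[sel]) / sum(sel)
  }
  idx <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 4), ]
  null <- apply(idx, 1, function(r) stat_for(labs[as.integer(r)]))
  obs <- stat_for(labs)
  exact <- mean(abs(null) >= abs(obs) - 1e-12)
  expect_lt(abs(res$p_value - exact), 0.03)
  expect_equal(res$observed, obs)
})

test_that("quartile shuffle holds its size under an exchangeable null", {
  # rating-independent miss probability => quartile labels exchangeable;
  # rejection rate at alpha = 0.05 stays within Monte-Carlo error
  n_studies <- 300
  rejections <- vapply(seq_len(n_studies), function(s) {
    set.seed(4000 + s)
    n_mov <- 16
    tab <- data.frame(
      participant_id = rep(paste0("p", 1:4), each = 2 * n_mov),
      experiment_id = "e1",
      prevalence_condition = rep(rep(c("high", "low"), each = n_mov), 4),
      session_order = "first",
      movie_id = rep(paste0("m", 1:n_mov), 8),
      hazard_present = TRUE,
      response_yes = runif(8 * n_mov) > 0.3,
      median_rating = rep(seq(0.1, 0.9, length.out = n_mov), 8),
      quartile = rep(rep(c("Q1", "Q2", "Q3", "Q4"), each = n_mov / 4), 8),
      stringsAsFactors = FALSE)
    p <- permute_quartile_shuffle(tab, focal_quartile = "Q4", B = 99,
                                  seed = s)$p_value
    p <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  # binomial error around 0.05 with 300 studies
  expect_gt(rate, 0.05 - 4 * sqrt(0.05 * 0.95 / n_studies))
  expect_lt(rate, 0.05 + 4 * sqrt(0.05 * 0.95 / n_studies))
})

test_that("permutation p-values always lie in (0, 1]", {
  set.seed(8)
  for (i in 1:20) {
    pairs <- lapply(1:5, function(j)
      list(high = runif(1), low = runif(1)))
    names(pairs) <- paste0("p", 1:5)
    res <- permute_condition_swap(pairs, stat_mean_diff, B = 19, seed = i)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("Bonferroni control divides alpha by the family size", {
  p20 <- setNames(runif(20), paste0("t", 1:20))
  b <- bonferroni(p20, alpha = 0.05)
  expect_equal(attr(b, "critical_alpha"), 0.0025)

  b1 <- bonferroni(c(only = 0.03), alpha = 0.05)
  expect_equal(attr(b1, "critical_alpha"), 0.05)
  expect_true(b1$significant)

  b16 <- bonferroni(setNames(runif(16), paste0("t", 1:16)), alpha = 0.05)
  expect_equal(attr(b16, "critical_alpha"), 0.05 / 16)
  expect_equal(attr(b16, "critical_alpha"), 0.003125)

  expect_error(bonferroni(numeric(0)), "empty")
})
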