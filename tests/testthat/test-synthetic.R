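# Synthetic-data generator: stimulus sets, rating panels, simulated
# experiments, and the observer model's analytic predictions.

test_that("stimulus sets honor counts, support, and the seed", {
  stim <- generate_stimulus_set(432, 944, seed = 1)
  expect_equal(nrow(stim), 1376)
  expect_equal(sum(stim$hazard_present), 432)
  expect_false(any(duplicated(stim$movie_id)))
  expect_true(all(stim$latent_hazardousness >= 0 &
                    stim$latent_hazardousness <= 1))
  expect_identical(stim, generate_stimulus_set(432, 944, seed = 1))
  expect_false(identical(stim$latent_hazardousness,
                         generate_stimulus_set(432, 944,
                                               seed = 2)$latent_hazardousness))

  degen <- generate_stimulus_set(1, 1, present_dist = dist_point(0.5),
                                 absent_dist = dist_point(0.5), seed = 9)
  expect_equal(degen$latent_hazardousness, c(0.5, 0.5))
})

test_that("latent means match the analytic distribution means", {
  pd <- dist_beta(5, 3)   # mean 0.625, var computed below
  ad <- dist_beta(2, 10)  # mean 1/6
  stim <- generate_stimulus_set(200, 200, present_dist = pd,
                                absent_dist = ad, seed = 7)
  beta_sd <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  m_p <- mean(stim$latent_hazardousness[stim$hazard_present])
  m_a <- mean(stim$latent_hazardousness[!stim$hazard_present])
  expect_lt(abs(m_p - pd$mean), 4 * beta_sd(5, 3) / sqrt(200))
  expect_lt(abs(m_a - ad$mean), 4 * beta_sd(2, 10) / sqrt(200))
  expect_gt(m_p, m_a)
})

test_that("rating panels: size, zero-noise identity, clamping, monotone fidelity", {
  stim <- generate_stimulus_set(432, 944, seed = 1)
  panel <- generate_ratings(stim, n_raters = 48, seed = 3)
  expect_equal(nrow(panel), 1376 * 48)
  expect_true(all(panel$rating >= 0 & panel$rating <= 1))

  small <- generate_stimulus_set(10, 10, seed = 2)
  noiseless <- generate_ratings(small, 5, rater_noise_sd = 0, seed = 4)
  med <- compute_median_ratings(noiseless)
  expect_equal(noiseless$rating,
               rep(small$latent_hazardousness, times = 5))
  expect_equal(med$median_rating[match(small$movie_id, med$movie_id)],
               small$latent_hazardousness)

  # median ratings track latent hazardousness more faithfully when rater
  # noise is small than when it is large
  s100 <- generate_stimulus_set(50, 50, seed = 5)
  rho <- sapply(c(0.05, 0.8), function(sd) {
    m <- compute_median_ratings(
      generate_ratings(s100, 48, rater_noise_sd = sd, seed = 6))
    cor(m$median_rating[match(s100$movie_id, m$movie_id)],
        s100$latent_hazardousness, method = "spearman")
  })
  expect_gt(rho[1], rho[2])

  expect_error(generate_ratings(s100[0, ], 48), "empty")
})

test_that("sessions honor designed prevalence exactly and are deterministic", {
  st <- tiny_study(seed = 11, n_participants = 3)
  tr <- st$trials
  per <- aggregate(hazard_present ~ participant_id + prevalence_condition,
                   tr, sum)
  expect_true(all(per$hazard_present[per$prevalence_condition == "high"] ==
                    round(0.5 * st$design$n_trials_high)))
  expect_true(all(per$hazard_present[per$prevalence_condition == "low"] ==
                    round(0.1 * st$design$n_trials_low)))
  # session order counterbalanced: participant 1 high-first, 2 low-first
  first <- tr[tr$session_order == "first",
              c("participant_id", "prevalence_condition")]
  first <- unique(first)
  expect_equal(first$prevalence_condition[first$participant_id == "e1_p01"],
               "high")
  expect_equal(first$prevalence_condition[first$participant_id == "e1_p02"],
               "low")
  # no movie repeats within a session
  by_sess <- split(tr$movie_id, paste(tr$participant_id,
                                      tr$prevalence_condition))
  expect_false(any(vapply(by_sess, anyDuplicated, integer(1)) > 0))

  again <- simulate_experiment(st$design, st$observer, st$stimuli,
                               st$medians, seed = 13)
  expect_identical(st$trials, again)
})

test_that("insufficient stimuli raise a capacity error naming the session", {
  stim <- generate_stimulus_set(5, 50, seed = 1)
  med <- compute_median_ratings(generate_ratings(stim, 4, seed = 2))
  des <- experiment_design("e1", n_trials_high = 40, n_trials_low = 50,
                           n_participants = 1)
  expect_error(simulate_experiment(des, observer_params(), stim, med),
               "hazard-present movies for the high")
})

test_that("simulated response rates match the analytic observer expectation", {
  # deterministic-observer limit: huge slope, no lapse/motor errors =>
  # movies clearly above the criterion point are never missed
  stim <- generate_stimulus_set(40, 80, seed = 21)
  med <- compute_median_ratings(generate_ratings(stim, 8, seed = 22))
  obs0 <- observer_params(slope = 500, criterion_high = 250,
                          criterion_shift = 0, lapse_rate = 0,
                          motor_error_rate = 0)
  des <- experiment_design("e1", n_trials_high = 40, n_trials_low = 60,
                           prevalence_low = 0.1, n_participants = 2)
  tr <- simulate_experiment(des, obs0, stim, med, seed = 23)
  m <- merge_trials_ratings(tr, med)
  clear <- m$hazard_present & m$median_rating > 0.55
  expect_true(all(m$response_yes[clear]))

  # stochastic observer: empirical P(yes) per condition matches the
  # analytic expectation over the sampled movies within binomial error
  obs <- observer_params(slope = 8, criterion_high = 4,
                         criterion_shift = 1, lapse_rate = 0.02,
                         motor_error_rate = 0.02)
  stim2 <- generate_stimulus_set(432, 944, seed = 31)
  med2 <- compute_median_ratings(generate_ratings(stim2, 16, seed = 32))
  des2 <- design_preset(1)
  des2$n_participants <- 16
  tr2 <- simulate_experiment(des2, obs, stim2, med2, seed = 11)
  m2 <- merge_trials_ratings(tr2, med2)
  for (cond in c("high", "low")) {
    sub <- m2[m2$prevalence_condition == cond, ]
    expected <- mean(p_yes_analytic(obs, sub$median_rating, cond))
    tol <- 4 * sqrt(expected * (1 - expected) / nrow(sub))
    expect_lt(abs(mean(sub$response_yes) - expected), tol)
  }
})

test_that("null generator gives zero expected LPE; shifted generator a positive one", {
  # criterion_shift = 0: mean overall LPE across replicate studies is
  # within Monte-Carlo error of 0
  lpes <- vapply(1:20, function(s) {
    st <- tiny_study(seed = 100 + s, n_participants = 6,
                     criterion_shift = 0)
    cells <- miss_rates(st$merged, by_quartile = FALSE)
    lpe_miss(cells)$lpe
  }, numeric(1))
  se <- sd(lpes) / sqrt(length(lpes))
  expect_lt(abs(mean(lpes)), 4 * se + 1e-8)

  # criterion_shift = 1: simulated per-quartile LPEs are positive and
  # track the analytic logistic-model prediction
  stim <- generate_stimulus_set(200, 400, seed = 41)
  med <- compute_median_ratings(generate_ratings(stim, 16, seed = 42))
  obs <- observer_params(slope = 8, criterion_high = 4, criterion_shift = 1,
                         lapse_rate = 0, motor_error_rate = 0)
  des <- experiment_design("e1", prevalence_high = 0.5,
                           prevalence_low = 0.1, n_trials_high = 400,
                           n_trials_low = 400, n_participants = 64)
  tr <- simulate_experiment(des, obs, stim, med, seed = 43)
  m <- merge_trials_ratings(tr, med)
  obs_lpe <- lpe_miss(miss_rates(m, by_quartile = TRUE))

  qmap <- assign_quartiles(med[med$movie_id %in%
                                 stim$movie_id[stim$hazard_present], ])
  med_q <- merge(med, qmap$map)
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    r <- med_q$median_rating[med_q$quartile == q]
    analytic <- mean(1 - p_yes_analytic(obs, r, "low")) -
      mean(1 - p_yes_analytic(obs, r, "high"))
    got <- obs_lpe$lpe[obs_lpe$quartile == q]
    expect_gt(analytic, 0)
    expect_gt(got, 0)
    expect_lt(abs(got - analytic), 0.08)
  }
})

test_that("a simulated study round-trips through its text files", {
  study <- simulate_study(experiments = list(
    experiment_design("e1", n_trials_high = 30, n_trials_low = 40,
                      prevalence_low = 0.1, n_participants = 2)),
    seed = 5, n_present = 30, n_absent = 60, n_raters = 6)
  dir <- tempfile()
  paths <- write_simulated_study(study, dir, params = list(seed = 5))
  expect_true(all(file.exists(paths)))
  tr <- read_trials(paths[["trials"]])
  expect_equal(nrow(tr), nrow(study$trials))
  expect_equal(load_report(tr)$n_dropped, 0)
  ra <- read_ratings(paths[["ratings"]])
  expect_equal(nrow(ra), nrow(study$ratings))
})
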