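# Shared fixture builders and independent oracles.

# Small simulated experiment: everything downstream of the generator can
# be exercised quickly with known observer parameters.
tiny_study <- function(seed = 1, n_participants = 4, criterion_shift = 1,
                       n_present = 60, n_absent = 120,
                       n_trials_high = 60, n_trials_low = 80,
                       prevalence_low = 0.1, lapse_rate = 0.02,
                       motor_error_rate = 0.02, rater_noise_sd = 0.1) {
  stim <- generate_stimulus_set(n_present, n_absent, seed = seed)
  med <- compute_median_ratings(
    generate_ratings(stim, 8, rater_noise_sd = rater_noise_sd,
                     seed = seed + 1))
  des <- experiment_design("e1", prevalence_low = prevalence_low,
                           n_trials_high = n_trials_high,
                           n_trials_low = n_trials_low,
                           n_participants = n_participants)
  obs <- observer_params(criterion_shift = criterion_shift,
                         lapse_rate = lapse_rate,
                         motor_error_rate = motor_error_rate)
  trials <- simulate_experiment(des, obs, stim, med, seed = seed + 2)
  list(stimuli = stim, medians = med, design = des, observer = obs,
       trials = trials, merged = merge_trials_ratings(trials, med))
}

# Exhaustive condition-swap null: the statistic over all 2^n per-
# participant swap patterns; the Monte-Carlo p converges to this.
exact_swap_p <- function(data, statistic, alternative = "two.sided") {
  n <- length(data)
  observed <- statistic(data)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  null <- apply(patterns, 1, function(flips) {
    swapped <- data
    for (i in which(as.logical(flips)))
      swapped[[i]] <- list(high = data[[i]]$low, low = data[[i]]$high)
    statistic(swapped)
  })
  if (alternative == "two.sided")
    mean(abs(null) >= abs(observed) - 1e-12)
  else mean(null >= observed - 1e-12)
}

# Write a data.frame to a temp CSV and return the path.
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
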