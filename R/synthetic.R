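# Synthetic-data module: stimulus sets, rater panels, and simulated
# detection experiments from a signal-detection observer model.
#
# The generator exists so every downstream stage (ingest, psychometric
# fits, LPE statistics, permutation tests) can be exercised with known
# ground truth: the observer's criterion shift between prevalence
# conditions is the quantity the analysis is supposed to recover.

# ---- latent-hazardousness distributions -------------------------------

#' Distribution parameters on [0, 1]
#'
#' Small constructors for the sampling laws used by the stimulus and
#' rating generators. All laws are supported on \[0, 1\].
#'
#' @param shape1,shape2 Beta shape parameters (> 0).
#' @param min,max uniform bounds inside \[0, 1\].
#' @param value point-mass location in \[0, 1\].
#' @return an object of class `latent_dist` with fields `kind`, the
#'   parameters, and `mean` (the analytic mean, used by tests).
#' @examples
#' d <- dist_beta(5, 3)
#' d$mean  # 5 / 8
#' @export
dist_beta <- function(shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  structure(list(kind = "beta", shape1 = shape1, shape2 = shape2,
                 mean = shape1 / (shape1 + shape2)),
            class = "latent_dist")
}

#' @rdname dist_beta
#' @export
dist_uniform <- function(min = 0, max = 1) {
  if (min < 0 || max > 1 || min >= max)
    stop_input("uniform bounds must satisfy 0 <= min < max <= 1")
  structure(list(kind = "uniform", min = min, max = max,
                 mean = (min + max) / 2),
            class = "latent_dist")
}

#' @rdname dist_beta
#' @export
dist_point <- function(value) {
  if (value < 0 || value > 1)
    stop_input("point mass must lie in [0, 1]")
  structure(list(kind = "point", value = value, mean = value),
            class = "latent_dist")
}

sample_latent <- function(dist, n) {
  if (!inherits(dist, "latent_dist"))
    stop_input("distribution parameters must be built with dist_beta(), ",
               "dist_uniform() or dist_point()")
  switch(dist$kind,
         beta    = stats::rbeta(n, dist$shape1, dist$shape2),
         uniform = stats::runif(n, dist$min, dist$max),
         point   = rep(dist$value, n))
}

# ---- stimulus sets ----------------------------------------------------

#' Generate a synthetic stimulus set
#'
#' Creates a set of "road movies" with a binary hazard-present annotation
#' and a latent hazardousness value in \[0, 1\]. Defaults emulate a
#' naturalistic hazard-video corpus: hazard-present movies span the
#' mid-to-high range of the scale (so rating quartiles are non-degenerate)
#' while hazard-absent movies concentrate near the safe end.
#'
#' @param n_present,n_absent counts of hazard-present / hazard-absent
#'   movies (each >= 1).
#' @param present_dist,absent_dist latent-hazardousness laws (see
#'   [dist_beta()]).
#' @param seed integer seed; identical arguments give identical output.
#' @return a data.frame with columns `movie_id`, `hazard_present`
#'   (logical) and `latent_hazardousness`.
#' @examples
#' stim <- generate_stimulus_set(432, 944, seed = 1)
#' table(stim$hazard_present)
#' @export
generate_stimulus_set <- function(n_present, n_absent,
                                  present_dist = dist_beta(5, 3),
                                  absent_dist = dist_beta(2, 10),
                                  seed = 1) {
  stopifnot(n_present >= 1, n_absent >= 1)
  n <- n_present + n_absent
  lat <- with_seed(seed, {
    c(sample_latent(present_dist, n_present),
      sample_latent(absent_dist, n_absent))
  })
  data.frame(
    movie_id = sprintf("m%05d", seq_len(n)),
    hazard_present = rep(c(TRUE, FALSE), c(n_present, n_absent)),
    latent_hazardousness = lat,
    stringsAsFactors = FALSE
  )
}

# ---- rater panel ------------------------------------------------------

#' Generate a panel of hazardousness ratings
#'
#' Each rater rates every movie on \[0, 1\]. Ratings are the movie's
#' latent hazardousness plus additive zero-mean Gaussian noise, clamped
#' to \[0, 1\]; only the per-movie median enters the downstream analysis,
#' so this simple noise model suffices.
#'
#' @param stimuli a stimulus set from [generate_stimulus_set()].
#' @param n_raters number of raters (>= 1); the emulated panel has 48.
#' @param rater_noise_sd standard deviation of the additive noise
#'   (0 means every rating equals the latent value).
#' @param seed integer seed.
#' @return a data.frame with columns `rater_id`, `movie_id`, `rating`.
#' @export
generate_ratings <- function(stimuli, n_raters = 48, rater_noise_sd = 0.1,
                             seed = 1) {
  if (is.null(stimuli) || nrow(stimuli) == 0)
    stop_input("empty stimulus set")
  stopifnot(n_raters >= 1, rater_noise_sd >= 0)
  n_mov <- nrow(stimuli)
  ratings <- with_seed(seed, {
    noise <- stats::rnorm(n_mov * n_raters, mean = 0, sd = rater_noise_sd)
    clamp01(rep(stimuli$latent_hazardousness, times = n_raters) + noise)
  })
  data.frame(
    rater_id = rep(sprintf("r%02d", seq_len(n_raters)), each = n_mov),
    movie_id = rep(stimuli$movie_id, times = n_raters),
    rating = ratings,
    stringsAsFactors = FALSE
  )
}

# ---- observer and design parameters -----------------------------------

#' Signal-detection observer parameters
#'
#' The observer responds "hazard present" with probability
#' `lapse/2 + (1 - lapse) * plogis(slope * rating - criterion)`, where the
#' criterion is `criterion_high` in the high-prevalence session and
#' `criterion_high + criterion_shift` in the low-prevalence session
#' (a conservative shift under low prevalence produces an LPE). The
#' emitted response is then inverted with probability `motor_error_rate`,
#' modelling response-execution slips independent of the decision.
#'
#' @param slope psychometric slope, logit units per unit rating (> 0).
#' @param criterion_high logit criterion under high prevalence; the
#'   high-prevalence 50% threshold is `criterion_high / slope`.
#' @param criterion_shift additional criterion under low prevalence
#'   (>= 0; 0 gives a null observer with no LPE).
#' @param lapse_rate stimulus-independent lapse probability in \[0, 0.2\].
#' @param motor_error_rate probability the intended response is inverted,
#'   in \[0, 0.2\].
#' @return an `observer_params` object (a validated list).
#' @export
observer_params <- function(slope = 8, criterion_high = 4,
                            criterion_shift = 1, lapse_rate = 0.02,
                            motor_error_rate = 0.02) {
  if (slope <= 0) stop_input("slope must be > 0")
  if (criterion_shift < 0) stop_input("criterion_shift must be >= 0")
  if (lapse_rate < 0 || lapse_rate > 0.2)
    stop_input("lapse_rate must lie in [0, 0.2]")
  if (motor_error_rate < 0 || motor_error_rate > 0.2)
    stop_input("motor_error_rate must lie in [0, 0.2]")
  structure(list(slope = slope, criterion_high = criterion_high,
                 criterion_shift = criterion_shift, lapse_rate = lapse_rate,
                 motor_error_rate = motor_error_rate),
            class = "observer_params")
}

#' Observer preset by feedback regime
#'
#' Trial-wise feedback is, empirically, what sustains the conservative
#' criterion shift under low prevalence; regimes with feedback get a full
#' shift and the no-feedback regime a reduced one. These presets are a
#' modelling convenience for simulation studies, not a mechanistic claim.
#'
#' @param feedback_mode one of `"full"`, `"none"`, `"partial"`,
#'   `"response_correction"`.
#' @param ... overrides passed to [observer_params()].
#' @export
observer_preset <- function(feedback_mode = c("full", "none", "partial",
                                              "response_correction"), ...) {
  feedback_mode <- match.arg(feedback_mode)
  shift <- switch(feedback_mode,
                  full = 1, response_correction = 1, partial = 0.8,
                  none = 0.3)
  args <- list(...)
  if (is.null(args$criterion_shift)) args$criterion_shift <- shift
  do.call(observer_params, args)
}

#' Experiment design for a two-session prevalence manipulation
#'
#' Each participant completes one high-prevalence and one low-prevalence
#' session; the hazard-present trial count per session is
#' `round(prevalence * n_trials)`.
#'
#' @param experiment_id label for the experiment.
#' @param prevalence_high,prevalence_low hazard prevalences in (0, 1),
#'   with `prevalence_low < prevalence_high`.
#' @param n_trials_high,n_trials_low trials per session.
#' @param n_participants number of participants.
#' @param feedback_mode feedback regime (see [observer_preset()]).
#' @param session_order_counterbalanced alternate high-first / low-first
#'   across participants when `TRUE`.
#' @return an `experiment_design` object.
#' @export
experiment_design <- function(experiment_id, prevalence_high = 0.5,
                              prevalence_low = 0.04, n_trials_high = 440,
                              n_trials_low = 500, n_participants = 16,
                              feedback_mode = c("full", "none", "partial",
                                                "response_correction"),
                              session_order_counterbalanced = TRUE) {
  feedback_mode <- match.arg(feedback_mode)
  if (prevalence_low >= prevalence_high)
    stop_input("prevalence_low must be smaller than prevalence_high")
  if (any(c(prevalence_high, prevalence_low) <= 0) ||
      any(c(prevalence_high, prevalence_low) >= 1))
    stop_input("prevalences must lie in (0, 1)")
  stopifnot(n_trials_high >= 1, n_trials_low >= 1, n_participants >= 1)
  if (round(prevalence_high * n_trials_high) < 1 ||
      round(prevalence_low * n_trials_low) < 1)
    stop_input("each session must contain at least one hazard-present trial")
  structure(list(experiment_id = as.character(experiment_id),
                 prevalence_high = prevalence_high,
                 prevalence_low = prevalence_low,
                 n_trials_high = n_trials_high,
                 n_trials_low = n_trials_low,
                 n_participants = n_participants,
                 feedback_mode = feedback_mode,
                 session_order_counterbalanced =
                   isTRUE(session_order_counterbalanced)),
            class = "experiment_design")
}

#' Design presets for the five-experiment study
#'
#' Experiments 1-4 use 50% / 4% prevalence with 440 / 500 trials per
#' session and 16 participants, differing only in feedback regime (full,
#' none, partial, response correction). Experiment 5 lowers prevalence to
#' 10% / 1% with 480 / 580 trials and 32 participants.
#'
#' @param experiment integer 1..5.
#' @export
design_preset <- function(experiment) {
  stopifnot(experiment %in% 1:5)
  if (experiment == 5) {
    experiment_design("exp5", prevalence_high = 0.10, prevalence_low = 0.01,
                      n_trials_high = 480, n_trials_low = 580,
                      n_participants = 32, feedback_mode = "full")
  } else {
    fb <- c("full", "none", "partial", "response_correction")[experiment]
    experiment_design(paste0("exp", experiment), feedback_mode = fb)
  }
}

# ---- analytic response probability ------------------------------------

#' Analytic probability of a "hazard present" response
#'
#' Closed-form response probability of the synthetic observer for a movie
#' with a given median rating, including lapse and motor-error stages.
#' Used as the independent oracle for simulation tests and for the
#' generator's analytic LPE predictions.
#'
#' @param observer an [observer_params()] object.
#' @param rating median hazardousness rating(s) in \[0, 1\].
#' @param condition `"high"` or `"low"` prevalence.
#' @param motor_correction_factor multiplier on `motor_error_rate`
#'   (the response-correction regime uses 0.25; see
#'   [simulate_experiment()]).
#' @return vector of response probabilities in \[0, 1\].
#' @export
p_yes_analytic <- function(observer, rating, condition = c("high", "low"),
                           motor_correction_factor = 1) {
  condition <- match.arg(condition)
  crit <- observer$criterion_high +
    if (condition == "low") observer$criterion_shift else 0
  p_dec <- observer$lapse_rate / 2 +
    (1 - observer$lapse_rate) * stats::plogis(observer$slope * rating - crit)
  m <- observer$motor_error_rate * motor_correction_factor
  p_dec * (1 - m) + (1 - p_dec) * m
}

# ---- experiment simulation --------------------------------------------

session_condition_order <- function(design, participant_index, seed) {
  if (design$session_order_counterbalanced) {
    if (participant_index %% 2 == 1) c("high", "low") else c("low", "high")
  } else {
    with_seed(derive_seed(seed, participant_index, 99),
              sample(c("high", "low")))
  }
}

#' Simulate a two-session detection experiment
#'
#' For each participant, draws one high- and one low-prevalence session
#' (order counterbalanced across participants when the design requests
#' it). Within a session, `round(prevalence * n_trials)` hazard-present
#' movies and the complementary number of hazard-absent movies are drawn
#' without replacement from the stimulus set, and the observer model of
#' [observer_params()] generates each response from the movie's median
#' rating. Under the response-correction feedback regime the effective
#' motor error rate is multiplied by `motor_correction_factor`, emulating
#' observers catching their own slips before committing.
#'
#' Responses are seeded per participant and session, so the output is a
#' pure function of the arguments.
#'
#' @param design an [experiment_design()].
#' @param observer an [observer_params()].
#' @param stimuli a stimulus set covering enough present/absent movies for
#'   every session.
#' @param medians per-movie median ratings
#'   (see [compute_median_ratings()]); must cover every stimulus.
#' @param seed master integer seed.
#' @param motor_correction_factor factor applied to the motor error rate
#'   when `design$feedback_mode == "response_correction"` (default 0.25).
#' @return a data.frame of trials with columns `participant_id`,
#'   `experiment_id`, `prevalence_condition`, `session_order`, `movie_id`,
#'   `hazard_present`, `response_yes`.
#' @examples
#' stim <- generate_stimulus_set(40, 80, seed = 1)
#' med <- compute_median_ratings(generate_ratings(stim, 8, seed = 1))
#' des <- experiment_design("demo", n_trials_high = 40, n_trials_low = 50,
#'                          n_participants = 2)
#' trials <- simulate_experiment(des, observer_params(), stim, med, seed = 1)
#' head(trials)
#' @export
simulate_experiment <- function(design, observer, stimuli, medians,
                                seed = 1, motor_correction_factor = 0.25) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(observer, "observer_params"))
  med_lookup <- stats::setNames(medians$median_rating, medians$movie_id)
  missing_med <- setdiff(stimuli$movie_id, names(med_lookup))
  if (length(missing_med))
    stop_input("medians missing for ", length(missing_med), " movies")

  present_ids <- stimuli$movie_id[stimuli$hazard_present]
  absent_ids <- stimuli$movie_id[!stimuli$hazard_present]

  session_spec <- list(
    high = list(n = design$n_trials_high,
                n_present = round(design$prevalence_high *
                                    design$n_trials_high)),
    low = list(n = design$n_trials_low,
               n_present = round(design$prevalence_low *
                                   design$n_trials_low))
  )
  for (cond in names(session_spec)) {
    sp <- session_spec[[cond]]
    if (sp$n_present > length(present_ids))
      stop_input("not enough hazard-present movies for the ", cond,
                 "-prevalence session (need ", sp$n_present, ", have ",
                 length(present_ids), ")")
    if (sp$n - sp$n_present > length(absent_ids))
      stop_input("not enough hazard-absent movies for the ", cond,
                 "-prevalence session (need ", sp$n - sp$n_present,
                 ", have ", length(absent_ids), ")")
  }

  m_eff <- observer$motor_error_rate *
    if (design$feedback_mode == "response_correction")
      motor_correction_factor else 1

  out <- vector("list", design$n_participants * 2L)
  k <- 0L
  for (p in seq_len(design$n_participants)) {
    pid <- sprintf("%s_p%02d", design$experiment_id, p)
    conds <- session_condition_order(design, p, seed)
    for (s in 1:2) {
      cond <- conds[s]
      sp <- session_spec[[cond]]
      sub_seed <- derive_seed(seed, p, if (cond == "high") 1L else 2L)
      tab <- with_seed(sub_seed, {
        mov <- c(sample(present_ids, sp$n_present),
                 sample(absent_ids, sp$n - sp$n_present))
        truth <- rep(c(TRUE, FALSE), c(sp$n_present, sp$n - sp$n_present))
        ord <- sample.int(sp$n)
        mov <- mov[ord]; truth <- truth[ord]
        crit <- observer$criterion_high +
          if (cond == "low") observer$criterion_shift else 0
        p_dec <- observer$lapse_rate / 2 + (1 - observer$lapse_rate) *
          stats::plogis(observer$slope * med_lookup[mov] - crit)
        intended <- stats::rbinom(sp$n, 1L, p_dec)
        flip <- stats::rbinom(sp$n, 1L, m_eff)
        data.frame(participant_id = pid,
                   experiment_id = design$experiment_id,
                   prevalence_condition = cond,
                   session_order = if (s == 1) "first" else "second",
                   movie_id = mov,
                   hazard_present = truth,
                   response_yes = xor(intended == 1L, flip == 1L),
                   stringsAsFactors = FALSE)
      })
      k <- k + 1L
      out[[k]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- study-level convenience ------------------------------------------

#' Simulate a complete multi-experiment study
#'
#' Generates one shared stimulus set and rating panel, then simulates each
#' requested experiment with a feedback-matched observer preset. This is
#' the one-call entry point the analysis scripts and pipeline use.
#'
#' @param experiments integer vector of experiment presets (subset of 1:5),
#'   or a list of [experiment_design()] objects.
#' @param seed master seed.
#' @param n_present,n_absent stimulus counts (defaults emulate the
#'   1376-movie corpus: 432 present, 944 absent).
#' @param n_raters rater-panel size (default 48).
#' @param observer optional single observer used for every experiment;
#'   by default each experiment gets [observer_preset()] for its feedback
#'   regime.
#' @param ... further arguments to [generate_stimulus_set()] /
#'   [generate_ratings()].
#' @return list with `stimuli`, `ratings`, `medians`, `trials` (all
#'   experiments row-bound) and `designs`.
#' @export
simulate_study <- function(experiments = 1:5, seed = 1,
                           n_present = 432, n_absent = 944, n_raters = 48,
                           observer = NULL, ...) {
  dots <- list(...)
  stim_args <- dots[intersect(names(dots),
                              c("present_dist", "absent_dist"))]
  rate_args <- dots[intersect(names(dots), "rater_noise_sd")]
  stimuli <- do.call(generate_stimulus_set,
                     c(list(n_present = n_present, n_absent = n_absent,
                            seed = derive_seed(seed, 1)), stim_args))
  ratings <- do.call(generate_ratings,
                     c(list(stimuli = stimuli, n_raters = n_raters,
                            seed = derive_seed(seed, 2)), rate_args))
  medians <- compute_median_ratings(ratings)
  designs <- if (is.list(experiments)) experiments
             else lapply(experiments, design_preset)
  trials <- do.call(rbind, lapply(seq_along(designs), function(i) {
    des <- designs[[i]]
    obs <- observer %||% observer_preset(des$feedback_mode)
    simulate_experiment(des, obs, stimuli, medians,
                        seed = derive_seed(seed, 3, i))
  }))
  list(stimuli = stimuli, ratings = ratings, medians = medians,
       trials = trials, designs = designs)
}

#' Write a simulated study to delimited text files
#'
#' Emits `trials.csv` and `ratings.csv` in the same schemas the ingest
#' module reads, plus a `params.json` sidecar recording the generator
#' parameters and seed.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param params list of generator parameters to record in the sidecar.
#' @return invisibly, the paths written.
#' @export
write_simulated_study <- function(study, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             ratings = file.path(dir, "ratings.csv"),
             params = file.path(dir, "params.json"))
  utils::write.csv(study$trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(study$ratings, paths[["ratings"]], row.names = FALSE)
  jsonlite::write_json(params, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
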