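# Psychometric module: binomial models of "hazard present" responses as a
# function of median hazardousness rating, 50% thresholds, and the
# threshold-shift form of the low prevalence effect.

# ---- per-condition logistic fit ---------------------------------------

#' Fit a binomial psychometric function
#'
#' Maximum-likelihood logistic regression of yes-counts on a stimulus
#' value (here, median hazardousness rating):
#' `P(yes) = plogis(intercept + slope * x)`. Separation and
#' non-convergence are flagged, never silently returned as estimates.
#'
#' @param x stimulus values (>= 2 distinct values required).
#' @param k yes-counts per value.
#' @param n trial counts per value (`n >= k >= 0` elementwise).
#' @return a `logistic_fit`: list with `intercept`, `slope`, `covariance`
#'   (2x2), `log_likelihood`, `converged`, `diagnostic`.
#' @examples
#' x <- seq(0, 1, length.out = 9)
#' n <- rep(50, 9)
#' k <- rbinom(9, n, plogis(-4 + 8 * x))
#' fit_logistic(x, k, n)
#' @export
fit_logistic <- function(x, k, n) {
  stopifnot(length(x) == length(k), length(k) == length(n))
  if (any(k < 0) || any(n < k)) stop_input("need n >= k >= 0 elementwise")
  if (length(unique(x)) < 2)
    stop_input("x is constant: the slope is not identifiable (rank error)")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  # divergent MLE under separation: fitted probabilities pinned at 0/1
  mu <- stats::fitted(fit)
  pinned <- any(mu[n > 0] < 1e-7) && any(mu[n > 0] > 1 - 1e-7) &&
    all(mu[n > 0] < 1e-7 | mu[n > 0] > 1 - 1e-7)
  separated <- sep_warn || pinned
  converged <- fit$converged && !separated
  diagnostic <- if (separated) {
    "possible complete separation: fitted probabilities reached 0/1"
  } else if (!fit$converged) {
    "IRLS did not converge"
  } else NA_character_
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 covariance = unname(stats::vcov(fit)),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = converged, diagnostic = diagnostic,
                 n_obs = sum(n)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binomial psychometric fit\n")
  cat(sprintf("  intercept %.4f  slope %.4f  (n = %d, logLik %.2f)\n",
              x$intercept, x$slope, x$n_obs, x$log_likelihood))
  if (!x$converged) cat("  NOT converged:", x$diagnostic, "\n")
  invisible(x)
}

# Aggregate a merged table into per-movie binomial counts for one
# prevalence condition.
condition_counts <- function(table, condition) {
  sub <- table[table$prevalence_condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) stop_input("no trials in condition ", condition)
  key <- sub$movie_id
  k <- rowsum(as.integer(sub$response_yes), key)
  n <- rowsum(rep(1L, nrow(sub)), key)
  x <- tapply(sub$median_rating, key, `[`, 1)
  ids <- rownames(k)
  data.frame(movie_id = ids, x = as.numeric(x[ids]),
             k = as.integer(k), n = as.integer(n),
             stringsAsFactors = FALSE)
}

# ---- thresholds --------------------------------------------------------

#' 50% threshold of a fitted psychometric function
#'
#' The hazardousness level at which "hazard" and "no hazard" responses are
#' equally likely: the root of `plogis(intercept + slope * x) = 0.5`,
#' which is `-intercept / slope` in closed form. Defined only for a
#' positive slope.
#'
#' @param fit a `logistic_fit`, or a numeric vector
#'   `c(intercept, slope)` (a condition-specific fixed-effect pair).
#' @param condition,experiment_id optional labels carried on the result.
#' @return a `threshold`: list with `value` (rating units, unclamped),
#'   `clamped` (`TRUE` if the value falls outside \[0, 1\]), `condition`,
#'   `experiment_id`.
#' @export
threshold_from_fit <- function(fit, condition = NA_character_,
                               experiment_id = NA_character_) {
  if (inherits(fit, "logistic_fit")) {
    b0 <- fit$intercept; b1 <- fit$slope
  } else if (is.numeric(fit) && length(fit) == 2) {
    b0 <- fit[1]; b1 <- fit[2]
  } else stop_input("fit must be a logistic_fit or c(intercept, slope)")
  if (!is.finite(b1) || b1 <= 0)
    stop_input("threshold undefined: fitted slope is not positive")
  value <- -b0 / b1
  structure(list(value = value, clamped = value < 0 || value > 1,
                 condition = condition, experiment_id = experiment_id),
            class = "threshold")
}

#' @export
print.threshold <- function(x, ...) {
  cat(sprintf("50%% threshold: %.4f%s\n", x$value,
              if (x$clamped) " (outside [0, 1])" else ""))
  invisible(x)
}

# ---- mixed-effects model ----------------------------------------------

glmm_formula <- function(multi_experiment) {
  if (multi_experiment) {
    # predictors: rating, prevalence, experiment, and all interactions
    # involving the rating covariate
    cbind(k, n - k) ~ median_rating + prevalence_condition + experiment_id +
      median_rating:prevalence_condition + median_rating:experiment_id +
      median_rating:prevalence_condition:experiment_id +
      (1 | participant_id)
  } else {
    cbind(k, n - k) ~ median_rating * prevalence_condition +
      (1 | participant_id)
  }
}

# Aggregate trials to binomial counts per participant x movie x condition
# (x experiment); the covariate is the movie's median rating.
glmm_aggregate <- function(table) {
  key <- interaction(table$participant_id, table$movie_id,
                     table$prevalence_condition, drop = TRUE)
  k <- rowsum(as.integer(table$response_yes), key)
  n <- rowsum(rep(1L, nrow(table)), key)
  first <- !duplicated(key)
  agg <- table[first, c("participant_id", "experiment_id",
                        "prevalence_condition", "movie_id",
                        "median_rating")]
  ids <- as.character(key[first])
  agg$k <- as.integer(k[ids, 1])
  agg$n <- as.integer(n[ids, 1])
  rownames(agg) <- NULL
  agg
}

#' Fit the binomial mixed-effects detection model
#'
#' Logit mixed model for the probability of a "hazard present" response
#' with fixed effects for median hazardousness rating, prevalence
#' condition, experiment, and all interactions involving the rating, plus
#' a participant random intercept. Trials are aggregated to binomial
#' counts per participant x movie x condition before fitting. The
#' marginal likelihood is maximized by adaptive Gauss-Hermite quadrature
#' (`nAGQ` nodes; 1 = Laplace), falling back to Laplace if quadrature
#' fails.
#'
#' Prevalence uses treatment coding with reference `"high"`, and
#' experiment with the first experiment as reference, so the intercept
#' and `median_rating` coefficients describe the high-prevalence
#' reference-experiment psychometric function; `contrasts = "sum"`
#' refits with sum-to-zero coding, which is the coding under which
#' [wald_type3()] tests of non-maximal terms are the classical Type III
#' tests.
#'
#' @param table merged analysis table (see [merge_trials_ratings()]).
#' @param nAGQ adaptive quadrature nodes (default 10).
#' @param contrasts `"treatment"` (default) or `"sum"`.
#' @return a `glmm_fit`: list with `fixed_effects`, `standard_errors`,
#'   `vcov_fixed`, `assign` (term index of each coefficient),
#'   `term_labels`, `random_intercept_variance`, `log_likelihood`,
#'   `n_obs` (Bernoulli trials), `rating_coef_per_unit`,
#'   `rating_coef_per_0.1`, `converged`, `messages`, and the underlying
#'   `model` (a `glmerMod`).
#' @export
fit_binomial_glmm <- function(table, nAGQ = 10,
                              contrasts = c("treatment", "sum")) {
  contrasts <- match.arg(contrasts)
  if (length(unique(table$participant_id)) < 2)
    stop_input("need >= 2 participants")
  if (!all(c("high", "low") %in% table$prevalence_condition))
    stop_input("both prevalence conditions must be present")
  agg <- glmm_aggregate(table)
  agg$prevalence_condition <- factor(agg$prevalence_condition,
                                     levels = c("high", "low"))
  agg$experiment_id <- factor(agg$experiment_id)
  agg$participant_id <- factor(agg$participant_id)
  multi <- nlevels(agg$experiment_id) > 1
  ctr <- if (contrasts == "sum") "contr.sum" else "contr.treatment"
  ctr_list <- c(list(prevalence_condition = ctr),
                if (multi) list(experiment_id = ctr))

  fml <- glmm_formula(multi)
  fit_once <- function(q) {
    lme4::glmer(fml, data = agg, family = stats::binomial(), nAGQ = q,
                contrasts = ctr_list)
  }
  model <- tryCatch(fit_once(nAGQ), error = function(e) {
    if (nAGQ != 1) fit_once(1) else stop(e)
  })

  fe <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(V))
  vc <- as.data.frame(lme4::VarCorr(model))
  ri_var <- vc$vcov[vc$grp == "participant_id"][1]
  msgs <- unlist(model@optinfo$conv$lme4$messages) %||% character(0)
  singular <- lme4::isSingular(model)
  if (singular)
    warning("participant random-intercept variance is (near) zero; ",
            "estimates returned", call. = FALSE)
  converged <- model@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs))
  mm_assign <- attr(stats::model.matrix(model), "assign")
  tl <- attr(stats::terms(stats::formula(model, fixed.only = TRUE)),
             "term.labels")

  structure(list(
    fixed_effects = fe,
    standard_errors = stats::setNames(se, names(fe)),
    vcov_fixed = V,
    assign = mm_assign,
    term_labels = tl,
    random_intercept_variance = ri_var,
    log_likelihood = as.numeric(stats::logLik(model)),
    n_obs = sum(agg$n),
    rating_coef_per_unit = unname(fe["median_rating"]),
    rating_coef_per_0.1 = unname(fe["median_rating"]) / 10,
    converged = converged,
    messages = msgs,
    contrasts = contrasts,
    model = model
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial GLMM (participant random intercept)\n")
  cat(sprintf("  n = %d Bernoulli trials, logLik %.2f, RI variance %.4f\n",
              x$n_obs, x$log_likelihood, x$random_intercept_variance))
  cat(sprintf("  rating coefficient: %.4f per unit (%.4f per 0.1)\n",
              x$rating_coef_per_unit, x$rating_coef_per_0.1))
  if (!x$converged) cat("  NOT converged:", paste(x$messages, collapse = "; "),
                        "\n")
  invisible(x)
}

#' Coefficient table of a fitted GLMM
#'
#' @param fit a `glmm_fit`.
#' @return data.frame with term, estimate, standard error, z and p.
#' @export
glmm_coef_table <- function(fit) {
  est <- fit$fixed_effects
  se <- fit$standard_errors
  z <- est / se
  data.frame(term = names(est), estimate = unname(est),
             std_error = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

# ---- Type III Wald tests ----------------------------------------------

#' Wald chi-square test of a model term's coefficient block
#'
#' Computes `W = c' V^-1 c` for the block `c` of coefficients belonging to
#' `term`, with `V` the corresponding block of the fixed-effect
#' covariance; `W ~ chi-square(df)` with `df` the block size. For the
#' highest-order interaction this is the Type III test under any factor
#' coding; for lower-order terms, fit the model with `contrasts = "sum"`
#' to obtain the classical Type III decomposition.
#'
#' @param fit a `glmm_fit`.
#' @param term a fixed-effect term label (see `fit$term_labels`).
#' @return list with `chisq`, `df`, `p`, `term`.
#' @export
wald_type3 <- function(fit, term) {
  idx <- match(term, fit$term_labels)
  if (is.na(idx))
    stop_input("term '", term, "' not in model; available: ",
               paste(fit$term_labels, collapse = ", "))
  sel <- which(fit$assign == idx)
  if (!length(sel)) stop_input("no coefficients for term ", term)
  cvec <- fit$fixed_effects[sel]
  V <- fit$vcov_fixed[sel, sel, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("singular covariance block for term '", term,
            "'; using pseudo-inverse", call. = FALSE)
    MASS::ginv(V)
  })
  W <- as.numeric(t(cvec) %*% Vi %*% cvec)
  df <- length(sel)
  list(chisq = W, df = df, p = stats::pchisq(W, df, lower.tail = FALSE),
       term = term)
}

# ---- thresholds from the GLMM and the threshold LPE --------------------

#' Condition-specific threshold from the mixed model
#'
#' Evaluates the fixed-effect (population-level, random intercept at
#' zero) linear predictor of the fitted GLMM for one experiment x
#' prevalence cell at ratings 0 and 1, recovers that cell's intercept and
#' rating slope, and returns the 50% threshold `-intercept/slope`.
#'
#' @param fit a `glmm_fit`.
#' @param experiment_id experiment label present in the fitted data.
#' @param condition `"high"` or `"low"`.
#' @return a `threshold` (see [threshold_from_fit()]).
#' @export
threshold_from_glmm <- function(fit, experiment_id,
                                condition = c("high", "low")) {
  condition <- match.arg(condition)
  model <- fit$model
  fr <- stats::model.frame(model)
  nd <- data.frame(
    median_rating = c(0, 1),
    prevalence_condition = factor(condition, levels = c("high", "low"))
  )
  multi <- "experiment_id" %in% names(fr)
  if (multi) {
    exp_levels <- levels(fr$experiment_id) %||% unique(fr$experiment_id)
    if (!experiment_id %in% exp_levels)
      stop_input("experiment '", experiment_id, "' not in fitted data")
    nd$experiment_id <- factor(experiment_id, levels = exp_levels)
  }
  lp <- unname(stats::predict(model, newdata = nd, re.form = NA,
                              type = "link"))
  threshold_from_fit(c(lp[1], lp[2] - lp[1]), condition = condition,
                     experiment_id = experiment_id)
}

#' Threshold-shift low prevalence effect for one experiment
#'
#' The low-prevalence 50% threshold minus the high-prevalence threshold.
#' Positive values mean observers required a more hazardous movie before
#' responding "hazard present" when hazards were rare (an LPE, i.e. a
#' conservative criterion shift); negative values indicate the opposite,
#' prevalence-induced concept change (PICC).
#'
#' @param table merged analysis table.
#' @param experiment_id experiment to analyse (default: the single
#'   experiment in `table`).
#' @param method `"glmm"` (default): fit the mixed model to this
#'   experiment's trials and slice its fixed-effect psychometric
#'   functions; `"logistic"`: independent per-condition logistic fits
#'   pooling participants (the cheaper sensitivity mode, also used inside
#'   permutation iterations).
#' @param nAGQ quadrature nodes for the `"glmm"` method.
#' @return a `threshold_lpe`: list with `value` (low - high),
#'   `threshold_low`, `threshold_high`, `experiment_id`, `method`.
#' @export
threshold_lpe <- function(table, experiment_id = NULL,
                          method = c("glmm", "logistic"), nAGQ = 1) {
  method <- match.arg(method)
  if (is.null(experiment_id)) {
    experiment_id <- unique(table$experiment_id)
    if (length(experiment_id) != 1)
      stop_input("multiple experiments in table; give experiment_id")
  }
  sub <- table[table$experiment_id == experiment_id, , drop = FALSE]
  if (nrow(sub) == 0) stop_input("no trials for experiment ", experiment_id)
  if (method == "glmm") {
    fit <- fit_binomial_glmm(sub, nAGQ = nAGQ)
    th_hi <- threshold_from_glmm(fit, experiment_id, "high")
    th_lo <- threshold_from_glmm(fit, experiment_id, "low")
  } else {
    th_hi <- threshold_from_fit(fit_condition_logistic(sub, "high"),
                                condition = "high",
                                experiment_id = experiment_id)
    th_lo <- threshold_from_fit(fit_condition_logistic(sub, "low"),
                                condition = "low",
                                experiment_id = experiment_id)
  }
  structure(list(value = th_lo$value - th_hi$value,
                 threshold_low = th_lo$value,
                 threshold_high = th_hi$value,
                 experiment_id = experiment_id, method = method),
            class = "threshold_lpe")
}

# Per-condition pooled logistic fit of a merged (sub)table.
fit_condition_logistic <- function(table, condition) {
  cc <- condition_counts(table, condition)
  fit_logistic(cc$x, cc$k, cc$n)
}

#' @export
print.threshold_lpe <- function(x, ...) {
  cat(sprintf(
    "Threshold LPE (%s, %s): %.4f  [low %.4f - high %.4f]\n",
    x$experiment_id, x$method, x$value, x$threshold_low, x$threshold_high))
  invisible(x)
}
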