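# Pipeline module: configuration, end-to-end orchestration (simulate or
# ingest -> merge -> fit -> LPE statistics -> permutation tests ->
# tables), and tidy tables for plotting. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Build a pipeline configuration
#'
#' Exactly one of `input` (paths to existing trial/rating files) or
#' `generator` (synthetic-study parameters) must be supplied.
#'
#' @param input list with `trials_path`, `ratings_path` and optional
#'   `trial_columns` / `rating_columns` maps.
#' @param generator list of [simulate_study()] arguments (`experiments`,
#'   `seed`, `n_present`, `n_absent`, `n_raters`, ...).
#' @param model list: `threshold_method` (`"glmm"` or `"logistic"`),
#'   `nAGQ` (quadrature nodes for the pooled fit).
#' @param permutation list: `B` iterations, `seed`, `alternative`.
#' @param bootstrap list: `B` resamples for figure confidence intervals,
#'   `seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            model = list(), permutation = list(),
                            bootstrap = list()) {
  if (is.null(input) == is.null(generator))
    stop_input("exactly one of 'input' or 'generator' must be given")
  if (!is.null(input) &&
      (is.null(input$trials_path) || is.null(input$ratings_path)))
    stop_input("input needs trials_path and ratings_path")
  model <- utils::modifyList(list(threshold_method = "glmm", nAGQ = 1),
                             model)
  permutation <- utils::modifyList(
    list(B = 1000, seed = 1, alternative = "two.sided"), permutation)
  bootstrap <- utils::modifyList(list(B = 10000, seed = 1), bootstrap)
  structure(list(input = input, generator = generator, model = model,
                 permutation = permutation, bootstrap = bootstrap),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(input = raw$input, generator = raw$generator,
                  model = raw$model %||% list(),
                  permutation = raw$permutation %||% list(),
                  bootstrap = raw$bootstrap %||% list())
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

acquire_data <- function(config) {
  if (!is.null(config$generator)) {
    study <- do.call(simulate_study, config$generator)
    list(trials = study$trials, medians = study$medians,
         reports = list(source = "generator"))
  } else {
    trials <- read_trials(config$input$trials_path,
                          config$input$trial_columns %||%
                            default_trial_columns())
    ratings <- read_ratings(config$input$ratings_path,
                            config$input$rating_columns %||%
                              default_rating_columns())
    list(trials = trials, medians = compute_median_ratings(ratings),
         reports = list(source = "files",
                        trials = load_report(trials),
                        ratings = load_report(ratings)))
  }
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a study, merges trials with median ratings and
#' quartile labels, fits the pooled binomial GLMM, extracts per-experiment
#' threshold LPEs with condition-swap permutation p-values, computes
#' per-quartile miss-rate LPEs with condition-swap p-values and
#' top-vs-other quartile contrasts with quartile-shuffle p-values, applies
#' Bonferroni control within each family, and writes all tables plus a
#' run log to `out_dir`. Rerunning with the same configuration reproduces
#' the statistical outputs exactly (all randomness is seeded from the
#' configuration).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report bundle (a list with the merged table,
#'   fits, LPE tables, permutation results and the summary table).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "ingest"
  bundle <- list(config = config)
  on.exit({
    if (!is.null(bundle$failed_stage))
      message("pipeline aborted in stage: ", bundle$failed_stage)
  })
  fail <- function(e) {
    bundle$failed_stage <<- stage
    manifest <- list(failed_stage = stage, error = conditionMessage(e),
                     completed = names(bundle))
    jsonlite::write_json(manifest, file.path(out_dir, "partial_manifest.json"),
                         auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    dat <- acquire_data(config)
    stage <- "merge"
    merged <- merge_trials_ratings(dat$trials, dat$medians)
    bundle$merged <- merged
    write_merged(merged, file.path(out_dir, "merged.csv"))

    stage <- "fit"
    glmm <- fit_binomial_glmm(merged, nAGQ = config$model$nAGQ)
    bundle$glmm <- glmm
    utils::write.csv(glmm_coef_table(glmm),
                     file.path(out_dir, "glmm_coefficients.csv"),
                     row.names = FALSE)
    wald <- NULL
    if ("median_rating:prevalence_condition:experiment_id" %in%
        glmm$term_labels)
      wald <- wald_type3(glmm,
                         "median_rating:prevalence_condition:experiment_id")
    bundle$wald_threeway <- wald
    jsonlite::write_json(
      list(fixed_effects = as.list(glmm$fixed_effects),
           standard_errors = as.list(glmm$standard_errors),
           covariance = glmm$vcov_fixed,
           random_intercept_variance = glmm$random_intercept_variance,
           log_likelihood = glmm$log_likelihood, n_obs = glmm$n_obs,
           rating_coef_per_0.1 = glmm$rating_coef_per_0.1,
           converged = glmm$converged, messages = glmm$messages,
           wald_threeway = wald),
      file.path(out_dir, "glmm_fit.json"), auto_unbox = TRUE, digits = NA)

    stage <- "lpe"
    experiments <- unique(merged$experiment_id)
    pcfg <- config$permutation
    cells_q <- miss_rates(merged, by_quartile = TRUE)
    cells_all <- miss_rates(merged, by_quartile = FALSE)
    bundle$miss_cells <- cells_q
    bundle$lpe_quartile <- lpe_miss(cells_q)
    bundle$lpe_overall <- lpe_miss(cells_all)
    bundle$proportional <- proportional_lpe(cells_q)
    utils::write.csv(bundle$lpe_quartile,
                     file.path(out_dir, "lpe_quartile.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$proportional,
                     file.path(out_dir, "proportional_lpe.csv"),
                     row.names = FALSE)

    stage <- "permute"
    perms <- list()
    table1 <- NULL
    for (i in seq_along(experiments)) {
      eid <- experiments[i]
      sub <- merged[merged$experiment_id == eid, , drop = FALSE]
      th <- threshold_lpe(sub, eid, method = config$model$threshold_method,
                          nAGQ = config$model$nAGQ)
      th_perm <- permute_condition_swap(
        pair_condition_trials(sub), stat_threshold_diff, B = pcfg$B,
        seed = derive_seed(pcfg$seed, i, 1), alternative = pcfg$alternative)
      row <- data.frame(experiment_id = eid, threshold_lpe = th$value,
                        threshold_p = th_perm$p_value,
                        stringsAsFactors = FALSE)
      perms[[paste0(eid, "_threshold")]] <- th_perm
      cells_e <- cells_q[cells_q$experiment_id == eid, , drop = FALSE]
      for (q in c("Q1", "Q2", "Q3", "Q4")) {
        qi <- match(q, c("Q1", "Q2", "Q3", "Q4"))
        pairs <- pair_miss_cells(cells_e, q)
        qp <- permute_condition_swap(
          pairs, stat_mean_diff, B = pcfg$B,
          seed = derive_seed(pcfg$seed, i, 1 + qi),
          alternative = pcfg$alternative)
        row[[paste0("lpe_", q)]] <- qp$observed
        row[[paste0("p_", q)]] <- qp$p_value
        perms[[paste0(eid, "_", q)]] <- qp
      }
      for (q in c("Q1", "Q2", "Q3")) {
        qi <- match(q, c("Q1", "Q2", "Q3"))
        cp <- permute_quartile_shuffle(
          sub, focal_quartile = "Q4", contrast = q, B = pcfg$B,
          seed = derive_seed(pcfg$seed, i, 10 + qi),
          alternative = pcfg$alternative)
        perms[[paste0(eid, "_Q4_vs_", q)]] <- cp
      }
      table1 <- rbind(table1, row)
    }
    bundle$permutations <- perms
    bundle$table1 <- table1

    stage <- "multiplicity"
    qp_family <- unlist(lapply(experiments, function(eid)
      stats::setNames(
        as.numeric(table1[table1$experiment_id == eid,
                          paste0("p_", c("Q1", "Q2", "Q3", "Q4"))]),
        paste0(eid, "_", c("Q1", "Q2", "Q3", "Q4")))))
    bundle$bonferroni_quartile <- bonferroni(qp_family)
    contrast_names <- grep("_Q4_vs_", names(perms), value = TRUE)
    if (length(contrast_names)) {
      cp_family <- vapply(perms[contrast_names], `[[`, numeric(1),
                          "p_value")
      bundle$bonferroni_contrast <- bonferroni(cp_family)
    }
    utils::write.csv(table1, file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$bonferroni_quartile,
                     file.path(out_dir, "bonferroni_quartile.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(perms, function(p)
        list(observed = p$observed, p_value = p$p_value, B = p$B,
             seed = p$seed, scheme = p$scheme, n_units = p$n_units)),
      file.path(out_dir, "permutations.json"), auto_unbox = TRUE,
      digits = NA)

    stage <- "log"
    log <- list(
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("roadlpe")),
      config_hash = config_hash(config),
      permutation_seed = pcfg$seed, permutation_B = pcfg$B,
      source = dat$reports$source,
      n_trials = nrow(merged),
      n_participants = length(unique(merged$participant_id)),
      exclusions = list(
        merge_dropped = load_report(merged)$n_dropped,
        lpe_overall_excluded = sum(bundle$lpe_overall$n_excluded),
        lpe_quartile_excluded = sum(bundle$lpe_quartile$n_excluded)))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle$run_log <- log
  }, error = fail)
  invisible(bundle)
}

# ---- figure tables -----------------------------------------------------

bootstrap_ci <- function(values, B, seed) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 1)
    return(c(lower = values, upper = values))
  means <- with_seed(seed, {
    vapply(seq_len(B), function(b)
      mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  })
  stats::setNames(stats::quantile(means, c(0.025, 0.975), names = FALSE),
                  c("lower", "upper"))
}

#' Tidy tables for plotting
#'
#' From a completed [run_pipeline()] bundle, emits (1) a per-movie
#' response-proportion vs median-rating table with fitted psychometric
#' curve samples per experiment x condition, and (2) a per-quartile
#' miss-rate table with percentile-bootstrap 95% confidence intervals
#' over participants (seeded; a single participant collapses the CI to
#' the point estimate).
#'
#' @param bundle list returned by [run_pipeline()].
#' @param out_dir output directory for the delimited-text tables.
#' @return invisibly, a list with `psychometric` (points + curves) and
#'   `quartile_miss` data.frames.
#' @export
make_figure_tables <- function(bundle, out_dir) {
  if (is.null(bundle$merged) || is.null(bundle$miss_cells))
    stop_input("bundle incomplete: run_pipeline() output required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  merged <- bundle$merged
  grid <- seq(0, 1, by = 0.01)

  psy <- do.call(rbind, lapply(unique(merged$experiment_id), function(eid) {
    sub <- merged[merged$experiment_id == eid, , drop = FALSE]
    do.call(rbind, lapply(c("high", "low"), function(cond) {
      cc <- condition_counts(sub, cond)
      fit <- fit_logistic(cc$x, cc$k, cc$n)
      rbind(
        data.frame(experiment_id = eid, prevalence_condition = cond,
                   kind = "movie", x = cc$x, y = cc$k / cc$n,
                   n = cc$n, stringsAsFactors = FALSE),
        data.frame(experiment_id = eid, prevalence_condition = cond,
                   kind = "curve", x = grid,
                   y = stats::plogis(fit$intercept + fit$slope * grid),
                   n = NA_integer_, stringsAsFactors = FALSE))
    }))
  }))
  utils::write.csv(psy, file.path(out_dir, "fig_psychometric.csv"),
                   row.names = FALSE)

  bcfg <- bundle$config$bootstrap
  cells <- bundle$miss_cells
  groups <- unique(cells[c("experiment_id", "prevalence_condition",
                           "quartile")])
  qm <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    v <- cells$miss_rate[cells$experiment_id == g$experiment_id &
                           cells$prevalence_condition ==
                             g$prevalence_condition &
                           cells$quartile == g$quartile]
    ci <- bootstrap_ci(v, bcfg$B, derive_seed(bcfg$seed, i))
    data.frame(g, mean_miss_rate = mean(v, na.rm = TRUE),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               n_participants = sum(!is.na(v)), stringsAsFactors = FALSE)
  }))
  rownames(qm) <- NULL
  utils::write.csv(qm, file.path(out_dir, "fig_quartile_miss.csv"),
                   row.names = FALSE)
  invisible(list(psychometric = psy, quartile_miss = qm))
}
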