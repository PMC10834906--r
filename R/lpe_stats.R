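# LPE statistics module: hazardousness quartiles, miss-rate LPE
# statistics, proportional LPE, within-participant permutation tests and
# Bonferroni control.
#
# Sign convention throughout: LPE = low-prevalence minus high-prevalence,
# so positive values mean observers missed more hazards (or required a
# higher threshold) when hazards were rare.

# ---- quartiles --------------------------------------------------------

#' Assign hazardousness quartiles to hazard-present movies
#'
#' Cut points are the 25/50/75% empirical quantiles of the median ratings
#' (linear interpolation, the [stats::quantile()] type-7 default). A
#' movie whose median equals a cut point goes to the lower quartile.
#' Q1 is the least hazardous quartile, Q4 the most hazardous.
#'
#' @param medians per-movie median table restricted to hazard-present
#'   movies (columns `movie_id`, `median_rating`; >= 4 movies).
#' @return list with `map` (data.frame `movie_id`, `quartile`) and
#'   `cut_points` (the three quantiles).
#' @export
assign_quartiles <- function(medians) {
  if (nrow(medians) < 4)
    stop_input("need >= 4 hazard-present movies to form quartiles")
  cuts <- stats::quantile(medians$median_rating, c(0.25, 0.5, 0.75),
                          names = FALSE)
  q <- cut(medians$median_rating,
           breaks = c(-Inf, cuts, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"),
           right = TRUE)
  list(map = data.frame(movie_id = medians$movie_id,
                        quartile = as.character(q),
                        stringsAsFactors = FALSE),
       cut_points = cuts)
}

# ---- miss-rate cells ---------------------------------------------------

#' Per-participant miss rates by condition (and quartile)
#'
#' A miss is a hazard-present trial answered "no hazard". Cells are
#' completed over the full participant x condition (x quartile) grid of
#' each experiment; a cell with zero hazard-present trials has
#' `miss_rate = NA` (undefined), never 0.
#'
#' @param table merged analysis table.
#' @param by_quartile split cells by hazardousness quartile (`TRUE`) or
#'   compute one overall cell per participant x condition (`FALSE`).
#' @return data.frame of cells: `participant_id`, `experiment_id`,
#'   `prevalence_condition`, `quartile` (`"overall"` when not split),
#'   `n_hazard_trials`, `n_misses`, `miss_rate`.
#' @export
miss_rates <- function(table, by_quartile = TRUE) {
  hz <- table[table$hazard_present, , drop = FALSE]
  if (nrow(hz) == 0) stop_input("table contains no hazard-present trials")
  qcol <- if (by_quartile) hz$quartile else rep("overall", nrow(hz))
  quart_levels <- if (by_quartile) c("Q1", "Q2", "Q3", "Q4") else "overall"

  grids <- lapply(split(hz, hz$experiment_id), function(sub) {
    expand.grid(participant_id = unique(sub$participant_id),
                prevalence_condition = c("high", "low"),
                quartile = quart_levels,
                stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  })
  grid <- do.call(rbind, Map(function(g, eid) {
    g$experiment_id <- eid; g
  }, grids, names(grids)))
  rownames(grid) <- NULL

  key <- paste(hz$participant_id, hz$prevalence_condition, qcol, sep = "\r")
  n <- rowsum(rep(1L, nrow(hz)), key)
  miss <- rowsum(as.integer(!hz$response_yes), key)
  gkey <- paste(grid$participant_id, grid$prevalence_condition,
                grid$quartile, sep = "\r")
  idx <- match(gkey, rownames(n))
  grid$n_hazard_trials <- ifelse(is.na(idx), 0L, n[idx, 1])
  grid$n_misses <- ifelse(is.na(idx), 0L, miss[idx, 1])
  grid$miss_rate <- ifelse(grid$n_hazard_trials > 0,
                           grid$n_misses / grid$n_hazard_trials, NA_real_)
  grid[c("participant_id", "experiment_id", "prevalence_condition",
         "quartile", "n_hazard_trials", "n_misses", "miss_rate")]
}

# ---- LPE statistics ----------------------------------------------------

#' Miss-rate low prevalence effect
#'
#' For each participant, the miss rate under low prevalence minus the
#' miss rate under high prevalence; the reported LPE is the mean of these
#' within-participant differences over the participants with both cells
#' defined (pairwise exclusion; excluded participants are counted).
#'
#' @param cells miss-rate cells from [miss_rates()].
#' @return data.frame with one row per experiment x quartile:
#'   `experiment_id`, `quartile`, `lpe`, `n_used`, `n_excluded`.
#' @export
lpe_miss <- function(cells) {
  out <- do.call(rbind, lapply(
    split(cells, list(cells$experiment_id, cells$quartile), drop = TRUE),
    function(sub) {
      wide <- merge(
        sub[sub$prevalence_condition == "high",
            c("participant_id", "miss_rate")],
        sub[sub$prevalence_condition == "low",
            c("participant_id", "miss_rate")],
        by = "participant_id", suffixes = c("_high", "_low"))
      ok <- !is.na(wide$miss_rate_high) & !is.na(wide$miss_rate_low)
      data.frame(
        experiment_id = sub$experiment_id[1], quartile = sub$quartile[1],
        lpe = if (any(ok))
          mean(wide$miss_rate_low[ok] - wide$miss_rate_high[ok])
          else NA_real_,
        n_used = sum(ok), n_excluded = sum(!ok),
        stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$experiment_id, out$quartile), ]
}

#' Proportional low prevalence effect
#'
#' Ratio of the mean miss rate under low prevalence to the mean miss rate
#' under high prevalence (means over participants with both cells
#' defined). A ratio of 1 means no LPE; e.g. 3 means misses were three
#' times as frequent when hazards were rare. Undefined (NA, flagged) when
#' the high-prevalence mean is 0.
#'
#' @param cells miss-rate cells from [miss_rates()].
#' @return data.frame per experiment x quartile: `mean_low`, `mean_high`,
#'   `ratio`, `undefined` flag, `n_used`.
#' @export
proportional_lpe <- function(cells) {
  out <- do.call(rbind, lapply(
    split(cells, list(cells$experiment_id, cells$quartile), drop = TRUE),
    function(sub) {
      wide <- merge(
        sub[sub$prevalence_condition == "high",
            c("participant_id", "miss_rate")],
        sub[sub$prevalence_condition == "low",
            c("participant_id", "miss_rate")],
        by = "participant_id", suffixes = c("_high", "_low"))
      ok <- !is.na(wide$miss_rate_high) & !is.na(wide$miss_rate_low)
      m_hi <- if (any(ok)) mean(wide$miss_rate_high[ok]) else NA_real_
      m_lo <- if (any(ok)) mean(wide$miss_rate_low[ok]) else NA_real_
      undef <- is.na(m_hi) || m_hi == 0
      data.frame(
        experiment_id = sub$experiment_id[1], quartile = sub$quartile[1],
        mean_low = m_lo, mean_high = m_hi,
        ratio = if (undef) NA_real_ else m_lo / m_hi,
        undefined = undef, n_used = sum(ok),
        stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$experiment_id, out$quartile), ]
}

# ---- permutation engine ------------------------------------------------

permutation_result <- function(observed, null_distribution, B, seed,
                               scheme, alternative, n_units) {
  crit <- switch(alternative,
                 two.sided = abs(null_distribution) >=
                   abs(observed) - 1e-12,
                 greater = null_distribution >= observed - 1e-12,
                 less = null_distribution <= observed + 1e-12)
  structure(list(observed = observed,
                 null_distribution = null_distribution,
                 p_value = (sum(crit) + 1) / (B + 1),
                 B = B, seed = seed, scheme = scheme,
                 alternative = alternative, n_units = n_units),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s): observed %.4f, p = %.4g (B = %d, n = %d)\n",
    x$scheme, x$alternative, x$observed, x$p_value, x$B, x$n_units))
  invisible(x)
}

#' Within-participant condition-swap permutation test
#'
#' Builds a null distribution for a low-minus-high statistic by randomly
#' exchanging each participant's two prevalence-condition structures:
#' each iteration independently swaps, with probability 1/2 per
#' participant, the participant's `high` and `low` entries and recomputes
#' the statistic on the relabelled data. Pairing within participants is
#' preserved exactly. The p-value uses the add-one convention
#' `(count + 1) / (B + 1)`, so it is never exactly 0 and its floor at
#' B = 1000 is 1/1001 (reported as "p < 0.001").
#'
#' @param data named list with one entry per participant, each a list
#'   with elements `high` and `low` (any structure the statistic
#'   understands: miss rates, trial tables, ...). Participants missing a
#'   condition are excluded with a warning.
#' @param statistic function of such a list returning one number; it must
#'   read the condition from the element position (`$high` / `$low`), not
#'   from any label stored inside the data.
#' @param B number of iterations (>= 1; the emulated analyses use 1000).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default, |null| >= |observed|),
#'   `"greater"`, or `"less"`.
#' @return a `permutation_result`: `observed`, `null_distribution`,
#'   `p_value`, `B`, `seed`, `scheme`, `n_units`.
#' @examples
#' pairs <- list(p1 = list(high = 0.1, low = 0.4),
#'               p2 = list(high = 0.2, low = 0.5))
#' permute_condition_swap(pairs, stat_mean_diff, B = 99, seed = 1)
#' @export
permute_condition_swap <- function(data, statistic, B = 1000, seed = 1,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  stopifnot(B >= 1)
  complete <- vapply(data, function(d)
    is.list(d) && !is.null(d$high) && !is.null(d$low), logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " participant(s) missing a condition; excluded",
            call. = FALSE)
    data <- data[complete]
  }
  n <- length(data)
  if (n == 0) stop_input("no participant has both conditions")

  observed <- statistic(data)
  null_dist <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      flips <- stats::runif(n) < 0.5
      swapped <- data
      for (i in which(flips))
        swapped[[i]] <- list(high = data[[i]]$low, low = data[[i]]$high)
      statistic(swapped)
    }, numeric(1))
  })
  permutation_result(observed, null_dist, B, seed, "condition_swap",
                     alternative, n)
}

#' Pair per-participant structures by prevalence condition
#'
#' Helpers that build the paired input of [permute_condition_swap()].
#' `pair_miss_cells()` pairs each participant's miss rates (optionally
#' for one quartile); `pair_condition_trials()` pairs each participant's
#' raw trial rows, for statistics that refit psychometric functions.
#'
#' @param cells miss-rate cells from [miss_rates()].
#' @param quartile which quartile's cells to pair (default `"overall"`).
#' @return named list of `list(high = , low = )` per participant.
#' @export
pair_miss_cells <- function(cells, quartile = "overall") {
  sub <- cells[cells$quartile == quartile, , drop = FALSE]
  if (nrow(sub) == 0) stop_input("no cells for quartile ", quartile)
  out <- lapply(split(sub, sub$participant_id), function(d) {
    hi <- d$miss_rate[d$prevalence_condition == "high"]
    lo <- d$miss_rate[d$prevalence_condition == "low"]
    if (!length(hi) || !length(lo) || is.na(hi) || is.na(lo)) NULL
    else list(high = hi, low = lo)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' @rdname pair_miss_cells
#' @param table merged analysis table (one experiment).
#' @export
pair_condition_trials <- function(table) {
  lapply(split(table, table$participant_id), function(d) {
    list(high = d[d$prevalence_condition == "high", , drop = FALSE],
         low = d[d$prevalence_condition == "low", , drop = FALSE])
  })
}

#' Statistics for the condition-swap test
#'
#' `stat_mean_diff()` is the miss-rate LPE: the mean over participants of
#' (low - high). `stat_threshold_diff()` pools the relabelled trials,
#' refits one logistic psychometric function per condition, and returns
#' the 50%-threshold difference (low - high); iterations whose refit
#' leaves a threshold undefined return NA and are dropped from the null
#' with a warning-free count in the result's null distribution length.
#'
#' @param data paired list as built by [pair_miss_cells()] /
#'   [pair_condition_trials()].
#' @export
stat_mean_diff <- function(data) {
  mean(vapply(data, function(d) d$low - d$high, numeric(1)))
}

#' @rdname stat_mean_diff
#' @export
stat_threshold_diff <- function(data) {
  pooled <- function(which) {
    df <- do.call(rbind, lapply(data, `[[`, which))
    k <- rowsum(as.integer(df$response_yes), df$movie_id)
    n <- rowsum(rep(1L, nrow(df)), df$movie_id)
    x <- tapply(df$median_rating, df$movie_id, `[`, 1)
    ids <- rownames(k)
    fit_logistic(as.numeric(x[ids]), as.integer(k), as.integer(n))
  }
  th <- function(fit) tryCatch(threshold_from_fit(fit)$value,
                               error = function(e) NA_real_)
  th(pooled("low")) - th(pooled("high"))
}

# ---- quartile-shuffle permutation test --------------------------------

# Per-participant movie-level ingredients: one row per hazard-present
# movie the participant saw, with per-condition trial and miss counts.
quartile_ingredients <- function(table) {
  hz <- table[table$hazard_present & table$quartile != "none", ,
              drop = FALSE]
  if (nrow(hz) == 0)
    stop_input("no quartile-labelled hazard-present trials")
  lapply(split(hz, hz$participant_id), function(d) {
    key <- d$movie_id
    n_hi <- rowsum(as.integer(d$prevalence_condition == "high"), key)
    m_hi <- rowsum(as.integer(d$prevalence_condition == "high" &
                                !d$response_yes), key)
    n_lo <- rowsum(as.integer(d$prevalence_condition == "low"), key)
    m_lo <- rowsum(as.integer(d$prevalence_condition == "low" &
                                !d$response_yes), key)
    q <- tapply(d$quartile, key, `[`, 1)
    ids <- rownames(n_hi)
    list(quartile = as.character(q[ids]),
         n_high = as.integer(n_hi), miss_high = as.integer(m_hi),
         n_low = as.integer(n_lo), miss_low = as.integer(m_lo))
  })
}

# LPE of one quartile given (possibly permuted) movie labels: mean over
# participants of (miss_low - miss_high), pairwise exclusion inside every
# iteration.
quartile_lpe_from_ingredients <- function(ing, labels, quartile) {
  diffs <- vapply(seq_along(ing), function(i) {
    d <- ing[[i]]
    sel <- labels[[i]] == quartile
    n_hi <- sum(d$n_high[sel]); n_lo <- sum(d$n_low[sel])
    if (n_hi == 0 || n_lo == 0) return(NA_real_)
    sum(d$miss_low[sel]) / n_lo - sum(d$miss_high[sel]) / n_hi
  }, numeric(1))
  if (all(is.na(diffs))) NA_real_ else mean(diffs, na.rm = TRUE)
}

#' Quartile-shuffle permutation test
#'
#' Tests whether the miss-rate LPE of one hazardousness quartile (or the
#' difference between two quartiles' LPEs) could arise if quartile labels
#' were exchangeable. Each iteration permutes the quartile labels across
#' each participant's hazard-present movies (independently per
#' participant; movies carry their trials with them, so per-quartile
#' movie counts are preserved), recomputes the focal statistic, and
#' accumulates the null. Participants without trials in both conditions
#' for the focal quartile are excluded pairwise inside every iteration,
#' mirroring the observed-statistic rule.
#'
#' @param table merged analysis table (one experiment).
#' @param focal_quartile quartile whose LPE is tested (`"Q1"`..`"Q4"`).
#' @param contrast optional second quartile: the statistic becomes
#'   `LPE(focal) - LPE(contrast)`.
#' @param B iterations (default 1000).
#' @param seed integer seed.
#' @param alternative sidedness, as in [permute_condition_swap()].
#' @return a `permutation_result` with scheme `"quartile_shuffle"`.
#' @export
permute_quartile_shuffle <- function(table, focal_quartile,
                                     contrast = NULL, B = 1000, seed = 1,
                                     alternative = c("two.sided", "greater",
                                                     "less")) {
  alternative <- match.arg(alternative)
  stopifnot(B >= 1, focal_quartile %in% c("Q1", "Q2", "Q3", "Q4"))
  ing <- quartile_ingredients(table)
  labels0 <- lapply(ing, `[[`, "quartile")

  stat <- function(labels) {
    v <- quartile_lpe_from_ingredients(ing, labels, focal_quartile)
    if (!is.null(contrast))
      v <- v - quartile_lpe_from_ingredients(ing, labels, contrast)
    v
  }
  observed <- stat(labels0)
  if (is.na(observed))
    stop_input("observed statistic undefined: no participant has both ",
               "conditions in quartile ", focal_quartile)
  null_dist <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stat(lapply(labels0, sample))
    }, numeric(1))
  })
  permutation_result(observed, null_dist, B, seed, "quartile_shuffle",
                     alternative, length(ing))
}

# ---- multiplicity -----------------------------------------------------

#' Bonferroni familywise control
#'
#' Compares each p-value against `alpha / m`, with `m` the family size.
#' The emulated quartile-level family has 20 tests (5 experiments x 4
#' quartiles) and hence a corrected critical alpha of 0.0025 at
#' alpha = 0.05.
#'
#' @param p_values named numeric vector of p-values (one family).
#' @param alpha familywise alpha in (0, 1).
#' @return data.frame with `name`, `p`, `critical_alpha`, `significant`;
#'   the corrected critical alpha is also attached as attribute
#'   `critical_alpha`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop_input("empty p-value family")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  crit <- alpha / length(p_values)
  out <- data.frame(name = names(p_values) %||%
                      as.character(seq_along(p_values)),
                    p = as.numeric(p_values),
                    critical_alpha = crit,
                    significant = as.numeric(p_values) < crit,
                    stringsAsFactors = FALSE)
  attr(out, "critical_alpha") <- crit
  out
}
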