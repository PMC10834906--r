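---
title: "Methods: prevalence effects in road-hazard detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prevalence effects in road-hazard detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(roadlpe)
```

## The question and the quantities

The low prevalence effect (LPE) is the tendency to miss targets that
occur rarely. In hazard-detection tasks it shows up as a higher miss
rate when hazard-present videos make up, say, 4% of trials than when
they make up 50%. This package implements an analysis pipeline for
asking whether *perceived hazardousness* — a continuous rating of how
dangerous each road video looks — modulates that effect: are very
dangerous-looking hazards immune to the LPE, or are they missed more
under low prevalence just like ambiguous ones?

Two quantities carry the analysis:

* **Threshold-shift LPE.** "Hazard present" responses are modelled as a
  logistic function of the movie's median hazardousness rating. The 50%
  threshold is the rating at which "hazard" and "no hazard" responses
  are equally likely. The LPE is the low-prevalence threshold minus the
  high-prevalence threshold; a positive shift means observers demanded a
  more hazardous-looking video before saying "hazard" when hazards were
  rare (a conservative criterion shift). A negative shift would indicate
  the opposite phenomenon, prevalence-induced concept change (PICC).
* **Miss-rate LPE.** Restricted to hazard-present movies, split into
  hazardousness quartiles (Q1 least, Q4 most hazardous): per
  participant, the miss rate under low prevalence minus the miss rate
  under high prevalence, averaged over participants. Reported overall
  and per quartile, with a proportional variant (low/high miss-rate
  ratio) that expresses the effect multiplicatively.

Both statistics are inferential via within-participant permutation
tests, not asymptotic theory, because each participant contributes
exactly one paired pair of sessions.

## The synthetic observer and what it emulates

Real deposits of the detection and rating data exist, but the package
must be fully exercisable offline, so a signal-detection generator
(`generate_stimulus_set()`, `generate_ratings()`,
`simulate_experiment()`) produces studies with the same structure and a
known ground truth.

**Stimulus corpus.** 1376 movies: 432 hazard-present, 944 hazard-absent
(the corpus total and the hazard-present count match the emulated
stimulus set; the absent count is their difference). Latent
hazardousness is Beta(5, 3) for present movies (broad, mid-to-high, so
rating quartiles of present movies are non-degenerate) and Beta(2, 10)
for absent movies (concentrated low). Both laws are config-exposed
(`dist_beta()`, `dist_uniform()`, `dist_point()`).

**Rating panel.** 48 raters, each rating every movie: the latent value
plus additive zero-mean Gaussian noise (default sd 0.1), clamped to
[0, 1]. Only the per-movie *median* enters the analysis, so a richer
rater model would add nothing the pipeline could detect.

**Observer.** A participant responds "hazard present" with probability

    p = lapse/2 + (1 - lapse) * plogis(slope * rating - criterion)

with `criterion = criterion_high` in the high-prevalence session and
`criterion_high + criterion_shift` in the low-prevalence session. The
emitted response is then inverted with probability `motor_error_rate`,
modelling response-execution slips. Defaults: slope 8 (logit units per
unit rating), criterion_high 4 — placing the high-prevalence threshold
at 0.5, the middle of the rating scale — criterion_shift 1 (analytic
threshold LPE = shift/slope = 0.125), lapse 0.02, motor error 0.02.
These are ordinary psychophysical magnitudes: a slope of 8 spans the
response range over roughly half the rating scale, and 2% lapse/motor
rates are typical of attentive online observers.

**Feedback regimes.** The five emulated experiments differ in trial-wise
feedback (full, none, partial, response correction) and, for experiment
5, in prevalence (10%/1% instead of 50%/4%). Feedback has no mechanism
in the generator; it only selects presets (`observer_preset()`):
criterion_shift 1 for full/response-correction feedback, 0.8 for
partial, 0.3 for none — qualitatively matching the empirical pattern
that removing feedback shrinks but does not reverse the shift. Under
response correction the effective motor error rate is multiplied by
0.25 (config-exposed), emulating observers catching their own slips.
These presets are a modelling convenience, not a claim about mechanism;
nothing downstream depends on them.

**Design arithmetic.** Sessions hold `round(prevalence * n_trials)`
hazard-present trials exactly (440/500 trials at 50%/4% for experiments
1–4 with 16 participants; 480/580 at 10%/1% for experiment 5 with 32),
movies drawn without replacement within a session, session order
counterbalanced. Every generator is a pure function of its arguments:
one master seed, with per-participant and per-session substreams
derived deterministically from it.

**What the generator does not emulate.** Participants are exchangeable —
there is no per-participant criterion or slope heterogeneity — so on
synthetic data the GLMM's participant random-intercept variance is
correctly estimated at (or near) zero and `lme4` reports a singular
fit; that warning is expected there. There are no sequential or
learning effects within a session, no reaction times, and no
stimulus-level structure beyond the latent hazardousness value. Passing
tests therefore certify the *pipeline arithmetic and inference
machinery* under known conditions, not the psychological model of any
real dataset.

## Ingest conventions

Deposited file dialects vary, so readers take a column map
(`default_trial_columns()`, `default_rating_columns()` are the synthetic
schema). Parsing is strict but non-fatal: rows with unparseable
condition/response fields or out-of-range ratings are dropped and
itemised in a load report (`load_report()`), and join conservation
(rows out + rows dropped = rows in) is an invariant. Movie IDs are
compared case-sensitively after whitespace trimming. Duplicate
(participant, condition, movie) rows are kept with a warning — no
deduplication rule is assumed. Aggregated (per-movie count) inputs can
be represented by repeating rows; the canonical path is trial-level.

## The mixed model

`fit_binomial_glmm()` fits, on trials aggregated to binomial counts per
participant × movie × prevalence condition,

    cbind(k, n-k) ~ rating + prevalence + experiment
                    + rating:prevalence + rating:experiment
                    + rating:prevalence:experiment
                    + (1 | participant)

i.e. main effects plus *all interactions involving the rating*, with a
participant random intercept and a logit link. Choices that needed
making:

* **Coding.** Treatment coding, reference = high prevalence and the
  first experiment, so the intercept/rating pair describes the
  reference psychometric function and thresholds can be sliced off
  directly. `contrasts = "sum"` refits with sum-to-zero coding, the
  coding under which `wald_type3()` on non-maximal terms is the
  classical Type III test; for the highest-order interaction the block
  Wald statistic is coding-invariant.
* **Rating scale.** The rating enters on its native [0, 1] scale,
  uncentred — the 50% threshold interpretation requires the raw scale.
  The headline slope is also reported per 0.1 rating units
  (`rating_coef_per_0.1`), the granularity at which rating differences
  are usually discussed.
* **Likelihood approximation.** Adaptive Gauss–Hermite quadrature with
  `nAGQ` nodes, default 10, which is cheap for a single scalar random
  effect; Laplace (`nAGQ = 1`) is the fallback and what the analysis
  scripts use for the pooled ~94k-trial fit, where quadrature refinement
  changes coefficients by far less than their standard errors.
* **Degenerate fits.** A singular random-intercept variance produces a
  warning, not an error, and the fixed effects are still returned; with
  the variance at zero they coincide with the independent-observations
  logistic fit (a tested invariant).

`wald_type3()` computes `W = c' V^{-1} c` over a term's coefficient
block with `df` = block size, using a pseudo-inverse (with a warning)
if the block covariance is singular. It is validated against an
independent implementation (`car::Anova`) in the tests.

## Thresholds

The 50% threshold of a logistic fit is `-intercept/slope`, defined only
for positive slope; the closed form agrees with numerical root-finding
to 1e-9 (a tested invariant). Values outside [0, 1] are returned with a
`clamped` flag rather than discarded. Two provenances are available,
because "thresholds from the fitted psychometric functions" admits two
readings:

* `threshold_lpe(method = "glmm")` (default): fit the mixed model and
  evaluate its fixed-effect linear predictor per experiment ×
  prevalence cell (population level, random intercept at zero) —
  matching the single-model description of the analysis;
* `threshold_lpe(method = "logistic")`: independent per-condition
  logistic fits pooling participants — the cheaper sensitivity mode.

On balanced synthetic data the two agree well inside estimation error
(tested). Permutation iterations always use the logistic mode: each
iteration must refit, and a per-iteration mixed-model refit would be
three orders of magnitude more expensive for no change in the test's
logic. The acceptance script uses the logistic mode for its observed
thresholds too, keeping the observed statistic and its null exactly
comparable.

## Quartiles, miss rates, and exclusion rules

Quartile cut points are the 25/50/75% empirical quantiles (linear
interpolation) of the hazard-present movies' median ratings; a movie
whose median equals a cut point goes to the *lower* quartile, so ties
never promote a movie. 432 distinct medians split 108/108/108/108.

A miss is a hazard-present trial answered "no hazard". Cells
(participant × condition × quartile) with zero hazard-present trials
are *undefined* (NA), never zero — at 4% prevalence a participant can
easily have no trials in some quartile, and treating that as a zero
miss rate would bias the LPE downward. The LPE is the mean of
within-participant (low − high) differences over participants with both
cells defined — not the difference of pooled rates — because the
permutation scheme operates within participants; excluded participants
are counted in a coverage report. The proportional LPE divides the mean
low-prevalence miss rate by the mean high-prevalence rate (same
pairwise-complete participants) and is flagged undefined when the
denominator is zero.

## Permutation inference

* **Condition swap** (`permute_condition_swap()`): each participant
  contributes exactly one high- and one low-prevalence structure; each
  iteration independently swaps the two with probability 1/2 per
  participant and recomputes the statistic. This is the exact
  within-participant exchangeability null for a paired design, and at
  small n the Monte-Carlo p converges to full enumeration of the 2^n
  swap patterns (tested at ±0.01 with B = 10,000).
* **Quartile shuffle** (`permute_quartile_shuffle()`): for
  quartile-vs-quartile comparisons, quartile labels are permuted across
  each participant's hazard-present *movies* (movies carry their trials
  with them), preserving per-quartile movie counts per participant. The
  pairwise-exclusion rule is re-applied inside every iteration so the
  observed statistic and the null are computed by identical code paths.
* **Sidedness and the p-value convention.** Two-sided by default
  (|null| ≥ |observed|), one-sided available. p = (count + 1)/(B + 1):
  never exactly zero, with floor 1/1001 at the conventional B = 1000 —
  consistent with reporting "p < 0.001" at that B.

Bonferroni control (`bonferroni()`) compares each p against alpha/m per
family. The quartile-level family is the 5 × 4 = 20 tests (critical
alpha 0.0025 at alpha 0.05); quartile-vs-quartile contrasts form their
own family. Family definitions are reported alongside the decisions
rather than silently assumed, since different groupings give slightly
different critical alphas (e.g. 0.0025 vs ~0.003).

## Problem sizes and numerical choices

The test suite and acceptance script choose sizes that make their
statistical assertions sharp while staying desk-scale:

* permutation-vs-enumeration agreement: 5–6 participants, B = 10,000;
* type-I error of the condition-swap test: 1,000 simulated null studies
  (criterion_shift 0) at the full 16-participant, 440/500-trial design,
  B = 200 per study, rejection rate required in [0.035, 0.065];
* threshold-LPE recovery: 64 participants × 4,000 trials against the
  analytic 0.125, tolerance ±0.03;
* threshold identity: 1,000 random converged fits, closed form vs
  root-finder at 1e-9;
* the acceptance script runs the full five-experiment study (96
  participants, ~94,000 trials) with B = 1,000 permutations.

Other numeric policies: complete separation in a logistic fit is
detected (fitted probabilities pinned at 0/1) and flagged as
non-convergence rather than returned silently; constant covariates
raise a rank error; figure confidence intervals are percentile
bootstraps over participants (10,000 resamples, seeded), collapsing to
the point estimate for a single participant.

## Limitations

The generator's exchangeable participants mean the random-intercept
machinery is exercised mostly at its boundary on synthetic data (the
recovery test injects heterogeneity explicitly). Feedback presets are
descriptive, not mechanistic. The pipeline does not model session-order
effects, stimulus range/variability effects on error rates, or a d′/
criterion decomposition — the threshold shift's sign is the only
criterion-direction claim it makes. Real deposited data can be analysed
by pointing `pipeline_config(input = ...)` at the files with an
appropriate column map, but no downloader is included.
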