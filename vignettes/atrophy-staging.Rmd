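---
title: "Modelling the sequence of brain atrophy in SCA3: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sequence of brain atrophy in SCA3: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atrostage` turns regional brain volumetry of SCA3 mutation carriers into a
disease staging framework. This vignette documents the models, the tunable
parameters and their defaults, the synthetic-data design, and the numerical
and design decisions a maintainer should know about.

## 1. Normative w-scoring

Healthy controls define the reference for each of the eight early-affected
regions. `fit_normative_model()` residualizes sequentially: first ordinary
least squares of raw volume on intracranial volume (ICV), then least squares
of that residual on age and sex; the residual SD defines the w unit. The
two-step form matches the conceptual order "ICV-corrected, then age- and
sex-adjusted"; a single joint regression is available via `joint = TRUE` and
differs only slightly when ICV correlates with sex. The age term is linear —
nothing in the problem dictates a functional form, and over the control age
range (~25–70 y) curvature in these regions is modest. Scanner covariates
are deliberately *not* part of the normative model: control scanner
diversity is too small to estimate them, so scanner effects are audited
post hoc (`scanner_effect_check()`) instead. Missing volumes or covariates
propagate as missing w-scores; they are never imputed, and the progression
model's likelihood simply skips missing dimensions.

By construction the fitting controls have mean w = 0, SD = 1 per region
(asserted to 1e-8 in the tests). With a 100-control reference, *applying*
the model to new data carries sampling error: the residual-SD estimate has
~7% relative error and the sex-offset standard error is ~0.2 control SDs.
This matters downstream (section 7).

## 2. The z-score event-based progression model

Severity is z = −w, so volume loss grows positive. An *atrophy event* is a
biomarker crossing z ∈ {1, 2, 3}; with eight regions this gives N = 24
events, and a disease *sequence* is an ordering of all 24 events subject to
each biomarker's thresholds appearing in increasing order. The expected
severity of biomarker *b* at stage *s* is piecewise-linear through (0, 0),
(p₁, 1), (p₂, 2), (p₃, 3) and (N, z_max); a visit's likelihood marginalises
the unknown stage over 0..N under a uniform prior.

Parameters and defaults:

* `sigma = 1` (z units): the data are w-scored, so unit noise is the natural
  scale. Configurable; tests of degenerate limits use other values (e.g. a
  flat-likelihood check at `sigma = 1e6`, concentration checks at 0.2).
* `z_max = 5`: the trajectory ceiling after the deepest threshold. Both
  values are conventional for z-score event-based models rather than
  quantities estimated from data.
* Uniform stage prior over 0..24.
* MCMC defaults (`ebm_control(profile = "full")`): 25 greedy starts, 1e5
  samples after 1e4 burn-in. The `test` profile (5 starts, 1e4 samples,
  1e3 burn-in) is used throughout the test suite and acceptance script and
  is ample at the n ≈ 300 scale.

**Greedy search.** The ML sequence is found by coordinate ascent: events are
visited in random order and each is moved to its best position inside the
window allowed by its within-biomarker neighbours, until a full pass yields
no improving single-event repositioning. This has the same fixed points as
evaluating all single-event moves and applying the steepest one, at a small
fraction of the cost; the saved time funds more restarts and the
cross-validation loops. The Metropolis chain proposes moving a random event
to a random valid position and accepts with the likelihood ratio; every
proposal provably respects the ordering constraint (asserted on samples in
the tests).

**Subtypes.** For k ≥ 2, `fit_subtypes()` splits the largest cluster of the
(k−1)-solution by the best of several random bipartitions and runs EM:
responsibilities, responsibility-weighted greedy refits, fraction updates,
to relative tolerance 1e-4. After convergence each cluster is re-polished
with multi-start greedy under the final responsibilities — without this,
clusters routinely end in *different local optima of near-identical weighted
likelihoods* on homogeneous data, exaggerating apparent heterogeneity.

**Staging.** `assign_stages()` reports the MAP stage under the
argmax-responsibility subtype, with posterior ties resolved to the lowest
stage (the conservative reading: least atrophy). Stage units are positions
along the event sequence; equal stage steps do not represent equal time
intervals.

## 3. Subtype-count selection

`select_model()` scores each candidate k by summed out-of-fold deviance
(CVIC) over subject-level folds. Two details matter:

1. **MCMC-sample averaging.** Out-of-fold likelihood is averaged over
   (thinned) posterior sequence samples, not evaluated at the ML sequence
   alone. A mixture of two near-identical sequences otherwise enjoys a pure
   model-averaging advantage over k = 1 — we observed redundant k = 2
   winning on single-sequence data in about half of the seeds with ML-only
   scoring.
2. **One-standard-error rule over repeated splits.** The selected k is the
   smallest whose CVIC is within one SE (of the fold-wise CVIC difference)
   of the minimum, with `repeats` independent fold splits stabilising both
   the margin and its SE estimate. On homogeneous data the k = 1 vs k = 2
   CVIC difference sits well inside fold noise, so a bare argmin from a
   single split is a coin flip; genuine subtype structure (e.g. two
   well-separated sequences) produces margins two orders of magnitude larger
   and is unaffected. `one_se_rule = FALSE` restores strict argmin.

## 4. Robustness metrics

`positional_density()` tabulates events × positions over MCMC samples (the
positional variance diagram); `bhattacharyya_mean()` is the mean over events
of Σ_s √(p_s q_s). Fold similarity trains one model per training split and
averages BC over the unordered fold pairs. The randomised baseline draws
pairs of uniform *valid* sequences and scores their one-hot densities
(mean ≈ 0.07 for the 24-event constrained space): the overlap expected with
no shared ordering information. `n_per_density` can smooth each density over
a bundle of random sequences, which raises the baseline smoothly towards 1
as the bundles approach the uniform positional marginal — published
intermediate baseline values for this model family correspond to such
spread constructions, whose exact recipe is not reproducible from public
descriptions; the unsmoothed default is the cleanest null.
`out_of_sample_staging()` compares full-sample with fold-trained stages
(MAE, Bland–Altman with 1.96 SD limits and a difference-on-mean slope for
proportional bias).

## 5. Staged clinical analyses

* `stage_change_model()`: stage ~ time with per-subject random intercepts
  and slopes, time in years from each subject's baseline; fitted on the
  longitudinal subset (subjects with ≥ 2 scans), since baseline-only
  subjects leave random slopes unidentifiable. Singular fits fall back to
  random intercepts with a flag. Group trends come from a time × ataxia
  interaction model via marginal linear trends (one interaction model, not
  stratified fits). Stages are treated as numeric.
* `monotonicity_report()` tabulates consecutive-scan stage changes —
  decreases violate the model's monotone-progression assumption and should
  be rare and of magnitude one.
* `stage_by_gait_ancova()`: stage ~ gait + age + sex with a nested-model F
  test and Tukey-adjusted pairwise contrasts (FDR across the contrast family
  reported alongside).
* `stage_regressions()`: time-from-onset → stage and stage → INAS with
  ataxia-status interactions; stage → SARA fitted per group and in the whole
  sample *without* a group × stage interaction, because conditioning a
  SARA-defined grouping on a SARA outcome model invites endogenous
  stratification. Standardized β come from refits with numeric variables
  z-scaled on the analysis sample. Onset ages missing from records are
  filled from a linear CAG → onset model fitted on reported rows, with a
  provenance flag per row so sensitivity analyses can drop estimated values.

## 6. Prognosis comparison and trial design

`build_model_set()` enumerates the clinical reference model (baseline age,
sex, CAG, INAS, gait × time, random intercept + slope) plus one spec per MRI
readout: atrophy stage, each single region's w-score, all w-scores, and the
global readout (the *sum of the eight w-scores* — summing before w-scoring
would need its own normative model and changes little). Gait is coded
ordinally 0–3 so that cross-validation folds cannot strand an unseen factor
level. AIC comparisons use maximum likelihood (not REML), as required when
fixed-effect structures differ. `cv_rmse_max_followup()` runs repeated
subject-level CV and predicts each test subject's SARA at their last
follow-up from *fixed effects only* — new subjects' random effects are
unobservable at baseline, so population-level prediction is the honest
out-of-sample protocol. Fold-level RMSE differences feed
`nadeau_bengio_test()`: t = mean(d) / √((1/J + n_test/n_train) var(d)),
df = J − 1 — the variance inflation that restores calibration when folds
share training data (the naive resampled t-test over-rejects; both are
exercised in calibration simulations in the tests).

`slope_sample_size()` implements the mixed-model-of-slopes formula (per-arm
n = ⌈2 (z_{1−α/2}+z_{power})² (σ_s² + σ_e²/Σ(t_j−t̄)²)/Δ²⌉; the quarterly
two-year schedule gives Σ(t_j−t̄)² = 3.75 exactly), verified against
`monte_carlo_power()`, a simulation oracle that fits the treatment × time
LMM per replicate (Wald normal p-values; at ~160 subjects the t vs normal
distinction is negligible). `enrichment_sweep()` re-estimates variance
components on each stage-eligible subsample (enrichment works *through* the
subsample's slope distribution; a fixed-variance mode exists), enforces the
≥ 15-subjects retention rule, and reports screen-failure rates as the
fraction of the screened baseline sample excluded. The unenriched reference
N uses the full sample's components.

## 7. The synthetic cohort generator

`cohort_config()` freezes the emulated study conditions: 100 controls and
322 carriers (tests use 300), a stage distribution mixing a preataxic-like
mass on stages 0–3 (weight 67/322) with a broad ataxic-like uniform over
2–24, stage progression 0.5 stages/year with stochastic rounding (mean-rate
preserving, never decreasing), visits at 0/1.2/2.4 years with 0.2-year
jitter, and SARA linked linearly to stage (intercept 1, 0.58 points/stage,
residual 1.5, floored at 0, capped at 40, half-point rounding). Ataxia
status is SARA ≥ 3; self-reported gait bands are fixed at <3 / 3–14.5 /
14.5–23 / >23. Per-subject SARA slopes are 0.10 + 0.02 × baseline stage +
N(0, 0.25) per year, so later stages progress faster — the coupling that
makes baseline stage prognostic and enrichment effective. INAS is Poisson
with mean 1 + 0.23 × stage, capped at 16. CAG (expanded ~N(69, 3)) maps to
onset age via an illustrative linear model (onset ≈ 200 − 2.3 × CAG ± 5);
carrier age is onset + a mild stage-dependent duration (0.45 y/stage ± 2),
keeping ages inside the control range with the familiar
younger-preataxic / older-ataxic structure. Normative volume parameters
(means, SDs, covariate slopes) are illustrative but realistic magnitudes
per region; their exact values are immaterial to the pipeline because
w-scoring is affine-equivariant (tested).

Two deliberate design points:

* **Noise persistence.** Severity noise has marginal SD `noise_sd` (default
  1) but is split into a subject-persistent component and a per-visit
  component (`noise_persistence = 0.95` of the variance persistent),
  mirroring the high scan–rescan reliability of automated volumetry.
  Independent per-visit noise would make consecutive-scan stage decreases
  ~30% of pairs — unlike any real longitudinal volumetry — while the
  persistent split yields the rare, mostly magnitude-one decreases the
  framework assumes. Controls always carry unit normative noise, so the
  noise-free patient limit (`noise_sd → 0`) remains w-scorable.
* **What the generator does not emulate**: scanner batch effects are off by
  default (a severity-offset hook exists for audits), INAS has no item
  structure, missingness is limited to unreported onset, and SARA's reduced
  sensitivity below 3 is not modelled. Passing tests therefore demonstrate
  correctness of the machinery under a faithful-but-idealised cohort, not
  robustness to multi-site messiness.

**End-to-end recovery and the 100-control limit.** On severities drawn
directly from the generative model, sequence recovery is exact without noise
and τ ≈ 0.93–0.96 at unit noise (n = 300). Through the full pipeline —
w-scoring referenced to 100 controls — τ drops to ≈ 0.86–0.93 depending on
the seed: normative sampling error (residual-SD scale error ~7%, sex-offset
SE ~0.2 SD) shifts each region's effective threshold-crossing positions by
up to about a stage, and the fitted sequence then has *higher* likelihood
than the generating one, so no amount of extra optimisation recovers it.
This is an inherent property of staging against a small normative reference,
not an implementation artifact (with a 2000-control reference τ rises to
≈ 0.95–0.98). The same mechanism makes out-of-fold selection occasionally
prefer k = 2 on pipeline-processed single-sequence data: the shared
w-scoring distortion is a small common deviation from any single sequence.
Selection-consistency checks therefore run on severities from the
generative model itself.

## 8. Numerical choices and degenerate inputs

Log-space likelihood accumulation with max-shifted log-sum-exp (terms below
e⁻³⁷ dropped); posterior ties broken to the lowest stage; degenerate inputs
fail loudly and by name (constant volume columns, single-sex controls,
fewer than 20 control visits, folds with < 2 subjects, cut-offs retaining
< 15 subjects, Δ = 0 sample sizes); all-missing visits are excluded with a
warning; visits with any missing biomarker keep a likelihood over the
remaining dimensions. Every stochastic routine takes an explicit seed, and
the generator derives independent substreams per table from one seed, so
identical configurations reproduce byte-identical cohorts.

## 9. Problem sizes used in the tests

The suite runs the default cohort at 300 carriers/100 controls with the
`test` MCMC profile; CVIC checks use n = 300 with 10 folds and 2000-sample
chains; CI-coverage uses 100 generator replicates of 60 subjects with stage
support 2–16 (away from the stage-24 ceiling, which otherwise attenuates
slopes — a real phenomenon users should expect near the end of the scale);
the Monte-Carlo power check uses 1000 replicates at the formula's n. These
sizes keep the full suite and the acceptance script to a few minutes on one
core while leaving all conclusions comfortably powered.

## 10. Known limitations

Harmonisation across scanners (ComBat-style) is out of scope — batch sizes
of one scan make it inapplicable here; the normative model is linear in age;
stages are analysed as numeric; no imputation anywhere; and external-cohort
replication — the real test of generalisability — is beyond what synthetic
data can show.
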