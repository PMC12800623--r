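# atrostage

Brain atrophy staging for spinocerebellar ataxia type 3 (SCA3).

SCA3 is an autosomal dominantly inherited, CAG-repeat neurodegenerative
disease in which regional brain volume loss is measurable on MRI before gait
ataxia manifests. `atrostage` implements a complete, tested pipeline that

1. converts regional brain volumes into control-referenced **w-scores**
   (intracranial-volume-corrected, age- and sex-adjusted deviations in
   control SD units; atrophy is negative w),
2. fits a **z-score event-based progression model** over the 24 atrophy
   events formed by eight early-affected regions (medulla oblongata, pons,
   midbrain, pallidum, superior cerebellar peduncle, cerebellar white matter,
   flocculonodular lobe, cerebellar anterior lobe) crossing the severity
   thresholds w = −1, −2, −3, with greedy + Metropolis MCMC sequence
   inference and optional subtype mixtures,
3. assigns each scan a maximum-a-posteriori **atrophy stage** (0–24),
4. quantifies robustness (positional-density Bhattacharyya overlap across
   cross-validation folds, out-of-sample staging error, Bland–Altman),
5. analyses stage against clinical course (mixed-model stage trends, gait
   ANCOVA, SARA/INAS regressions, prognosis model comparison with
   Nadeau–Bengio-corrected repeated-CV tests), and
6. sizes two-arm slope-outcome trials under stage-based prognostic
   enrichment.

Because real patient-level data of this kind are access-restricted, the
package ships a first-class **synthetic cohort generator** with known ground
truth (true event sequence, per-visit stages, per-subject SARA slopes), so
every stage of the pipeline can be verified end to end.

## The model

For biomarker *b* with threshold events at sequence positions
p₁ < p₂ < p₃ and severity z = −w, the expected severity at stage *s* is the
piecewise-linear curve through (0, 0), (p₁, 1), (p₂, 2), (p₃, 3), (N, z_max),
N = 24, z_max = 5. A sequence S has marginal likelihood

    L(S) = Π_i Σ_{s=0..N} P(s) Π_b N(z_ib ; g_b(s | S), σ) ,

with a uniform stage prior P(s) and σ = 1 (the data are w-scored). The ML
sequence is found by multi-start greedy ascent over single-event
repositionings and refined by a Metropolis chain whose proposals move a
random event within its valid window; positional uncertainty is summarised
from the post-burn-in samples. A visit's stage posterior is
P(s | z) ∝ P(s) Π_b N(z_b ; g_b(s), σ); the MAP stage is reported with ties
resolved to the lowest stage. Subtype mixtures (k ≥ 2) are fitted by EM over
responsibilities, responsibility-weighted sequence refits and mixture
fractions; the subtype count is chosen by cross-validated out-of-fold
deviance (CVIC) with MCMC-sample averaging and the one-standard-error rule.

Trial sample sizes use the mixed-model-of-slopes formula: with per-subject
slope variance σ_s² + σ_e²/Σ_j(t_j − t̄)² and detectable difference
Δ = e · mean slope,

    n per arm = ⌈ 2 (z_{1−α/2} + z_{power})² (σ_s² + σ_e²/Σ(t_j − t̄)²) / Δ² ⌉ .

## Worked example

```r
library(atrostage)

## simulate a cohort at the default study conditions
cfg <- cohort_config(n_patients = 300, seed = 7)
cohort <- generate_longitudinal(cfg, generate_cohort(cfg))
#> Synthetic SCA3 cohort: 100 control and 300 carrier baseline scans, 640 scans total

## control-referenced w-scoring
norm_model <- fit_normative_model(cohort$volumes)
wscores <- compute_wscores(norm_model, cohort$volumes)
carriers <- wscores[wscores$group == "SCA3" & wscores$visit_index == 1, ]

## fit the event-based progression model on baseline severities
events <- ebm_events()
fit <- fit_subtypes(severity_matrix(carriers), events, k = 1,
                    control = ebm_control(profile = "test"), seed = 1)
head(sequence_labels(fit$sequences[[1]], events), 6)
#> [1] "medulla_oblongata|z1"            "pons|z1"
#> [3] "cerebellar_white_matter|z1"      "midbrain|z1"
#> [5] "superior_cerebellar_peduncle|z1" "pons|z2"

## stage every scan and estimate progression over time
all_carriers <- wscores[wscores$group == "SCA3", ]
stages <- assign_stages(fit, severity_matrix(all_carriers))
vols <- cohort$volumes[cohort$volumes$group == "SCA3", ]
tab <- data.frame(subject_id = all_carriers$subject_id,
                  time = vols$time, stage = stages$map_stage)
stage_change_model(tab, by_group = FALSE)
#> Stage change: 0.49 stages/year (95% CI 0.41 to 0.57, p = 8.1e-27) [random-intercept fallback]

## recovery against the generator's ground truth
sequence_kendall(fit$sequences[[1]], cohort$truth$sequence, events)
#> [1] 0.8550725
```

The fitted ordering starts in the caudal brainstem with early white-matter
involvement, mirroring the generator's ground truth; staged follow-up scans
progress at ~0.5 stages/year, the generator's true rate. The Kendall τ of
0.86 against the true sequence reflects the irreducible sampling noise of a
100-control normative reference on top of unit severity noise — on
severities taken directly from the generative model the same fit recovers
the sequence exactly (noise-free) or with τ ≈ 0.95 (unit noise); see the
methods vignette.

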