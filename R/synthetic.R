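#' Default ground-truth atrophy sequence for synthetic cohorts
#'
#' A fixed, valid ordering of the 24 events used as the generator's ground
#' truth: atrophy ascends from the caudal brainstem (medulla, pons) with early
#' and fast white-matter involvement (pons and cerebellar white matter reach
#' the deepest threshold first), later basal ganglia and cerebellar cortex.
#'
#' @param events An [ebm_events()] object (default 8 regions x 3 thresholds).
#' @return Integer event-index sequence.
#' @export
default_true_sequence <- function(events = ebm_events()) {
  labels <- c(
    "medulla_oblongata|z1", "pons|z1", "cerebellar_white_matter|z1",
    "superior_cerebellar_peduncle|z1", "pons|z2",
    "cerebellar_white_matter|z2", "medulla_oblongata|z2", "midbrain|z1",
    "pons|z3", "cerebellar_white_matter|z3", "flocculonodular_lobe|z1",
    "pallidum|z1", "superior_cerebellar_peduncle|z2", "midbrain|z2",
    "medulla_oblongata|z3", "cerebellar_anterior_lobe|z1",
    "flocculonodular_lobe|z2", "pallidum|z2",
    "superior_cerebellar_peduncle|z3", "midbrain|z3",
    "cerebellar_anterior_lobe|z2", "flocculonodular_lobe|z3", "pallidum|z3",
    "cerebellar_anterior_lobe|z3")
  if (!identical(sort(labels), sort(events$table$label)))
    return(canonicalize_sequence(seq_len(events$n_events), events))
  sequence_from_labels(labels, events)
}

default_volume_model <- function(regions = sca3_regions()) {
  # illustrative normative parameters (mm^3): control mean, control SD, age
  # slope (per year), sex offset (male - female), ICV coefficient
  m <- data.frame(
    region = regions,
    mean = c(4600, 14500, 6200, 3600, 300, 22000, 950, 4800),
    sd = c(450, 1600, 600, 400, 40, 2600, 120, 550),
    age_slope = c(-8, -25, -10, -9, -0.4, -35, -1.5, -8),
    sex_offset = c(120, 400, 150, 100, 8, 600, 25, 130),
    icv_coef = c(0.0020, 0.0070, 0.0028, 0.0016, 0.00012, 0.0105, 0.0004,
                 0.0022),
    stringsAsFactors = FALSE
  )
  m[seq_along(regions), ]
}

#' Configuration of the synthetic SCA3 cohort generator
#'
#' Defaults emulate the modelled cohort: 100 healthy controls and 322 mutation
#' carriers, a two-group stage distribution (a preataxic-like mass on stages
#' 0-3 with weight 67/322 and a broad ataxic-like uniform over 2-24), stage
#' progression of 0.5 stages/year, follow-up visits about 1.2 years apart, and
#' SARA coupled linearly to stage (0.58 SARA points per stage). Controls always
#' carry unit normative noise in control-SD units; `noise_sd` scales the
#' severity noise of patients only, so the noise-free limit remains w-scorable.
#'
#' @param n_controls,n_patients Group sizes.
#' @param events Atrophy event set ([ebm_events()]).
#' @param true_sequence Ground-truth event ordering (integer indices).
#' @param stage_distribution Probability vector over stages 0..N.
#' @param stage_rate_per_year True stage progression rate (stages/year).
#' @param noise_sd Patient severity noise SD (z units).
#' @param noise_persistence Fraction of the severity noise variance that is
#'   subject-persistent across visits (default 0.95, mirroring the high
#'   scan-rescan reliability of automated volumetry: only the remaining
#'   variance is redrawn at each visit). The marginal per-visit noise SD is
#'   always `noise_sd`.
#' @param visit_schedule Visit offsets in years, starting at 0, increasing.
#' @param visit_jitter_sd SD of Gaussian jitter on follow-up offsets (years).
#' @param followup_fraction Fraction of patients with follow-up visits.
#' @param sara_link List: `intercept`, `slope_per_stage` (cross-sectional SARA
#'   per stage), `slope_base`, `slope_coupling` (per-subject SARA/year slope =
#'   base + coupling x baseline stage), `slope_sd`, `residual_sd`.
#' @param inas_link List: `base`, `per_stage` Poisson mean of the INAS count.
#' @param age_mean,age_sd,age_range Control age distribution (years).
#' @param sex_ratio Fraction female.
#' @param icv_model List: `mean`, `sd`, `male_offset` (mm^3).
#' @param volume_model Per-region normative parameters (see
#'   `default_volume_model`): control mean/SD, age slope, sex offset, ICV
#'   coefficient.
#' @param cag_model List: `mean`, `sd`, `normal_mean`, `normal_sd` repeat
#'   lengths.
#' @param onset_model List: `intercept`, `cag_slope`, `sd` mapping expanded CAG
#'   to gait-ataxia onset age (illustrative linear model), plus
#'   `years_per_stage` and `duration_sd` for the cross-sectional disease
#'   duration at a given stage (current age = onset age + duration).
#' @param onset_stage Continuous stage at which gait ataxia begins (used to tie
#'   disease duration to stage).
#' @param scanner List: `manufacturers`, `field_strengths`, `probs`,
#'   `severity_offsets` (z units added per scanner; batch-effect hook, default
#'   off).
#' @param z_max Trajectory ceiling of the generating model.
#' @param seed Integer seed; all randomness flows from it via fixed substreams.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 100, n_patients = 322,
                          events = ebm_events(),
                          true_sequence = default_true_sequence(events),
                          stage_distribution = NULL,
                          stage_rate_per_year = 0.5,
                          noise_sd = 1.0,
                          noise_persistence = 0.95,
                          visit_schedule = c(0, 1.2, 2.4),
                          visit_jitter_sd = 0.2,
                          followup_fraction = 0.4,
                          sara_link = list(intercept = 1.0,
                                           slope_per_stage = 0.58,
                                           slope_base = 0.10,
                                           slope_coupling = 0.02,
                                           slope_sd = 0.25,
                                           residual_sd = 1.5),
                          inas_link = list(base = 1.0, per_stage = 0.23),
                          age_mean = 44, age_sd = 14, age_range = c(25, 70),
                          sex_ratio = 0.5,
                          icv_model = list(mean = 1.5e6, sd = 1.3e5,
                                           male_offset = 9e4),
                          volume_model = default_volume_model(),
                          cag_model = list(mean = 69, sd = 3,
                                           normal_mean = 21, normal_sd = 4),
                          onset_model = list(intercept = 200,
                                             cag_slope = -2.3, sd = 5,
                                             years_per_stage = 0.45,
                                             duration_sd = 2),
                          onset_stage = 3.4,
                          scanner = list(manufacturers = "Siemens",
                                         field_strengths = 3.0, probs = 1,
                                         severity_offsets = 0),
                          z_max = 5, seed = 1L) {
  N <- events$n_events
  if (is.null(stage_distribution)) {
    pre <- rep(0, N + 1)
    pre[1:4] <- 1 / 4
    atax <- rep(0, N + 1)
    atax[3:(N + 1)] <- 1 / (N - 1)
    w_pre <- 67 / 322
    stage_distribution <- w_pre * pre + (1 - w_pre) * atax
  }
  cfg <- list(n_controls = n_controls, n_patients = n_patients,
              events = events, true_sequence = true_sequence,
              stage_distribution = stage_distribution,
              stage_rate_per_year = stage_rate_per_year, noise_sd = noise_sd,
              noise_persistence = noise_persistence,
              visit_schedule = visit_schedule,
              visit_jitter_sd = visit_jitter_sd,
              followup_fraction = followup_fraction, sara_link = sara_link,
              inas_link = inas_link, age_mean = age_mean, age_sd = age_sd,
              age_range = age_range, sex_ratio = sex_ratio,
              icv_model = icv_model, volume_model = volume_model,
              cag_model = cag_model, onset_model = onset_model,
              onset_stage = onset_stage, scanner = scanner, z_max = z_max,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  N <- cfg$events$n_events
  stopifnot(cfg$n_controls > 0, cfg$n_patients > 0,
            is_valid_sequence(cfg$true_sequence, cfg$events),
            length(cfg$stage_distribution) == N + 1,
            all(cfg$stage_distribution >= 0),
            sum(cfg$stage_distribution) > 0,
            cfg$noise_sd >= 0, cfg$stage_rate_per_year >= 0,
            cfg$noise_persistence >= 0, cfg$noise_persistence <= 1,
            cfg$visit_schedule[1] == 0,
            !is.unsorted(cfg$visit_schedule, strictly = TRUE),
            all(cfg$volume_model$sd > 0), cfg$sara_link$residual_sd > 0,
            cfg$icv_model$sd > 0)
  invisible(cfg)
}

# named substreams so each table has independent, reproducible randomness
substream <- function(cfg, name) {
  offs <- c(controls = 11L, patients = 37L, longitudinal = 59L, scanner = 83L)
  set.seed((cfg$seed + offs[[name]]) %% .Machine$integer.max)
}

round_half <- function(x) round(x * 2) / 2

gait_from_sara <- function(sara) {
  cut(sara, breaks = c(-Inf, 3, 14.5, 23, Inf), right = FALSE,
      labels = c("normal", "gait difficulties", "walking aid", "wheelchair"))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

volumes_from_w <- function(cfg, W, icv, age, male) {
  vm <- cfg$volume_model
  V <- matrix(NA_real_, nrow(W), nrow(vm),
              dimnames = list(NULL, vm$region))
  for (j in seq_len(nrow(vm))) {
    V[, j] <- vm$mean[j] + vm$icv_coef[j] * (icv - cfg$icv_model$mean) +
      vm$age_slope[j] * (age - cfg$age_mean) + vm$sex_offset[j] * male +
      W[, j] * vm$sd[j]
  }
  V
}

draw_scanner <- function(cfg, n) {
  sc <- cfg$scanner
  idx <- sample.int(length(sc$manufacturers), n, replace = TRUE,
                    prob = sc$probs)
  list(manufacturer = sc$manufacturers[idx],
       field_strength = sc$field_strengths[pmin(idx, length(sc$field_strengths))],
       severity_offset = sc$severity_offsets[pmin(idx, length(sc$severity_offsets))])
}

#' Generate a synthetic SCA3 cohort with known ground truth
#'
#' Controls sit at stage 0 with unit normative noise; patients draw a true
#' stage from `stage_distribution`, their biomarker severities follow the
#' piecewise-linear event trajectories of the generating sequence at that stage
#' plus `Normal(0, noise_sd)`, and volumes are back-transformed through the
#' normative volume model so that w-scoring recovers the severities. SARA is a
#' linear function of stage (floored at 0, capped at 40, rounded to half
#' points); gait status follows fixed SARA bands (normal < 3, gait
#' difficulties 3-14.5, walking aid 14.5-23, wheelchair > 23) and ataxia
#' status is SARA >= 3.
#'
#' @param config A [cohort_config()].
#' @return A list of class `sca3_cohort`: `volumes` (per-visit volume table),
#'   `clinical` (per-visit clinical table, carriers only), `truth` (ground
#'   truth: sequence, per-visit stages, per-subject SARA slopes), `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  events <- cfg$events
  N <- events$n_events
  regions <- cfg$volume_model$region

  # controls -----------------------------------------------------------------
  substream(cfg, "controls")
  nc <- cfg$n_controls
  c_age <- rtrunc_norm(nc, cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                       cfg$age_range[2])
  c_male <- as.numeric(runif(nc) > cfg$sex_ratio)
  c_icv <- rnorm(nc, cfg$icv_model$mean + cfg$icv_model$male_offset * c_male,
                 cfg$icv_model$sd)
  c_w <- matrix(rnorm(nc * length(regions)), nc)
  c_vol <- volumes_from_w(cfg, c_w, c_icv, c_age, c_male)
  controls <- data.frame(
    subject_id = sprintf("HC%03d", seq_len(nc)), visit_index = 1L, time = 0,
    group = "control", age = c_age, sex = ifelse(c_male == 1, "male", "female"),
    icv = c_icv, stringsAsFactors = FALSE
  )
  controls <- cbind(controls, as.data.frame(c_vol))

  # patients ------------------------------------------------------------------
  substream(cfg, "patients")
  np <- cfg$n_patients
  stage0 <- sample(0:N, np, replace = TRUE, prob = cfg$stage_distribution)
  cag <- round(rtrunc_norm(np, cfg$cag_model$mean, cfg$cag_model$sd, 60, 80))
  cag_normal <- round(rtrunc_norm(np, cfg$cag_model$normal_mean,
                                  cfg$cag_model$normal_sd, 13, 35))
  onset_true <- cfg$onset_model$intercept + cfg$onset_model$cag_slope * cag +
    rnorm(np, 0, cfg$onset_model$sd)
  # cross-sectional disease duration rises mildly with stage (heterogeneous
  # progression rates), keeping carrier ages inside the control age range
  tfo_true <- (stage0 - cfg$onset_stage) * cfg$onset_model$years_per_stage +
    rnorm(np, 0, cfg$onset_model$duration_sd)
  p_age <- pmax(onset_true + tfo_true, 18)
  p_male <- as.numeric(runif(np) > cfg$sex_ratio)
  p_icv <- rnorm(np, cfg$icv_model$mean + cfg$icv_model$male_offset * p_male,
                 cfg$icv_model$sd)
  G <- expected_trajectory(cfg$true_sequence, events, z_max = cfg$z_max)
  zt <- G[stage0 + 1L, , drop = FALSE]
  pers_sd <- cfg$noise_sd * sqrt(cfg$noise_persistence)
  visit_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_persistence)
  pers_noise <- matrix(rnorm(np * length(regions), 0, pers_sd), np,
                       dimnames = list(NULL, regions))
  z <- zt + pers_noise + matrix(rnorm(np * length(regions), 0, visit_sd), np)
  scan <- draw_scanner(cfg, np)
  z <- z + scan$severity_offset
  p_vol <- volumes_from_w(cfg, -z, p_icv, p_age, p_male)

  sl <- cfg$sara_link
  sara_latent <- sl$intercept + sl$slope_per_stage * stage0 +
    rnorm(np, 0, sl$residual_sd)
  sara <- round_half(pmin(pmax(sara_latent, 0), 40))
  true_slope <- sl$slope_base + sl$slope_coupling * stage0 +
    rnorm(np, 0, sl$slope_sd)
  inas <- pmin(rpois(np, cfg$inas_link$base + cfg$inas_link$per_stage * stage0),
               16)
  ataxic <- sara >= 3
  onset_reported <- ataxic & runif(np) < 0.95
  onset_age <- ifelse(onset_reported, round(onset_true, 1), NA_real_)

  sid <- sprintf("SCA%03d", seq_len(np))
  pat_vol <- data.frame(
    subject_id = sid, visit_index = 1L, time = 0, group = "SCA3",
    age = p_age, sex = ifelse(p_male == 1, "male", "female"), icv = p_icv,
    stringsAsFactors = FALSE
  )
  pat_vol <- cbind(pat_vol, as.data.frame(p_vol))
  controls$scanner_manufacturer <- "Siemens"
  controls$field_strength <- 3.0
  pat_vol$scanner_manufacturer <- scan$manufacturer
  pat_vol$field_strength <- scan$field_strength

  volumes <- rbind(controls, pat_vol)

  clinical <- data.frame(
    subject_id = sid, visit_index = 1L, time = 0,
    age = p_age, sex = ifelse(p_male == 1, "male", "female"),
    sara = sara, inas = inas,
    gait_status = as.character(gait_from_sara(sara)),
    ataxia_status = ifelse(ataxic, "ataxic", "preataxic"),
    cag_expanded = cag, cag_normal = cag_normal,
    onset_age = onset_age,
    onset_source = ifelse(onset_reported, "reported", NA_character_),
    time_from_onset = ifelse(onset_reported, p_age - onset_age, NA_real_),
    stringsAsFactors = FALSE
  )

  truth <- list(
    sequence = cfg$true_sequence,
    sequence_labels = sequence_labels(cfg$true_sequence, events),
    stages = data.frame(subject_id = sid, visit_index = 1L, time = 0,
                        true_stage = stage0, true_stage_cont = as.numeric(stage0),
                        stringsAsFactors = FALSE),
    subjects = data.frame(subject_id = sid, baseline_stage = stage0,
                          true_sara_slope = true_slope,
                          sara_latent = sara_latent,
                          onset_age_true = onset_true,
                          stringsAsFactors = FALSE),
    persistent_noise = cbind(data.frame(subject_id = sid,
                                        stringsAsFactors = FALSE),
                             as.data.frame(pers_noise))
  )
  structure(list(volumes = volumes, clinical = clinical, truth = truth,
                 config = cfg),
            class = "sca3_cohort")
}

#' Extend a baseline cohort with longitudinal visits
#'
#' A fraction of patients receives follow-up visits at the configured schedule
#' (with optional jitter). True stages advance at `stage_rate_per_year` with
#' stochastic rounding of the continuous expected progress (preserving the
#' mean rate) and never decrease; SARA advances at each subject's true slope;
#' volumes are regenerated from the advanced stage.
#'
#' @param config The [cohort_config()] used for the baseline cohort.
#' @param cohort A [generate_cohort()] result.
#' @return The cohort with follow-up rows appended to `volumes`, `clinical`
#'   and `truth$stages`.
#' @export
generate_longitudinal <- function(config, cohort) {
  cfg <- validate_cohort_config(config)
  if (!inherits(cohort, "sca3_cohort") || nrow(cohort$volumes) == 0)
    stop("empty or invalid baseline cohort")
  if (length(cfg$visit_schedule) < 2) return(cohort)
  events <- cfg$events
  N <- events$n_events
  regions <- cfg$volume_model$region
  substream(cfg, "longitudinal")

  base_cl <- cohort$clinical[cohort$clinical$visit_index == 1, ]
  np <- nrow(base_cl)
  fu_ids <- base_cl$subject_id[sample.int(np) <= round(cfg$followup_fraction * np)]
  subj <- cohort$truth$subjects
  G <- expected_trajectory(cfg$true_sequence, events, z_max = cfg$z_max)

  vol_rows <- list(); cl_rows <- list(); st_rows <- list()
  for (id in fu_ids) {
    b_vol <- cohort$volumes[cohort$volumes$subject_id == id &
                              cohort$volumes$visit_index == 1, ]
    b_cl <- base_cl[base_cl$subject_id == id, ]
    tr <- subj[subj$subject_id == id, ]
    prev_stage <- tr$baseline_stage
    prev_t <- 0
    for (j in seq_along(cfg$visit_schedule)[-1]) {
      t <- cfg$visit_schedule[j] +
        if (cfg$visit_jitter_sd > 0) rnorm(1, 0, cfg$visit_jitter_sd) else 0
      t <- max(t, prev_t + 0.1)
      delta <- cfg$stage_rate_per_year * t
      adv <- floor(delta) + rbinom(1, 1, delta - floor(delta))
      st <- min(max(tr$baseline_stage + adv, prev_stage), N)
      pn <- cohort$truth$persistent_noise
      z <- G[st + 1L, ] +
        as.numeric(pn[pn$subject_id == id, regions]) +
        rnorm(length(regions), 0,
              cfg$noise_sd * sqrt(1 - cfg$noise_persistence))
      vol <- volumes_from_w(cfg, matrix(-z, 1), b_vol$icv, b_vol$age + t,
                            as.numeric(b_vol$sex == "male"))
      vr <- b_vol
      vr$visit_index <- j
      vr$time <- t
      vr$age <- b_vol$age + t
      vr[regions] <- as.data.frame(vol)
      vol_rows[[length(vol_rows) + 1L]] <- vr

      sara_t <- round_half(pmin(pmax(
        tr$sara_latent + tr$true_sara_slope * t +
          rnorm(1, 0, cfg$sara_link$residual_sd), 0), 40))
      cr <- b_cl
      cr$visit_index <- j
      cr$time <- t
      cr$age <- b_cl$age + t
      cr$sara <- sara_t
      cr$inas <- min(rpois(1, cfg$inas_link$base + cfg$inas_link$per_stage * st),
                     16)
      cr$gait_status <- as.character(gait_from_sara(sara_t))
      cr$ataxia_status <- ifelse(sara_t >= 3, "ataxic", "preataxic")
      cr$time_from_onset <- ifelse(is.na(b_cl$time_from_onset), NA_real_,
                                   b_cl$time_from_onset + t)
      cl_rows[[length(cl_rows) + 1L]] <- cr

      st_rows[[length(st_rows) + 1L]] <- data.frame(
        subject_id = id, visit_index = j, time = t, true_stage = st,
        true_stage_cont = min(tr$baseline_stage + delta, N),
        stringsAsFactors = FALSE)
      prev_stage <- st
      prev_t <- t
    }
  }
  if (length(vol_rows)) {
    cohort$volumes <- rbind(cohort$volumes, do.call(rbind, vol_rows))
    cohort$clinical <- rbind(cohort$clinical, do.call(rbind, cl_rows))
    cohort$truth$stages <- rbind(cohort$truth$stages, do.call(rbind, st_rows))
    ord <- order(cohort$volumes$subject_id, cohort$volumes$visit_index)
    cohort$volumes <- cohort$volumes[ord, ]
    rownames(cohort$volumes) <- NULL
    ord <- order(cohort$clinical$subject_id, cohort$clinical$visit_index)
    cohort$clinical <- cohort$clinical[ord, ]
    rownames(cohort$clinical) <- NULL
    ord <- order(cohort$truth$stages$subject_id,
                 cohort$truth$stages$visit_index)
    cohort$truth$stages <- cohort$truth$stages[ord, ]
    rownames(cohort$truth$stages) <- NULL
  }
  cohort
}

#' @export
print.sca3_cohort <- function(x, ...) {
  cat(sprintf("Synthetic SCA3 cohort: %d control and %d carrier baseline scans, %d scans total\n",
              sum(x$volumes$group == "control" & x$volumes$visit_index == 1),
              sum(x$volumes$group == "SCA3" & x$volumes$visit_index == 1),
              nrow(x$volumes)))
  invisible(x)
}
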