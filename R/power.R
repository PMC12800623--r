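#' Two-arm slope-outcome trial design
#'
#' Defaults describe a two-year, placebo-controlled, parallel-group trial with
#' quarterly SARA assessments (9 visits at 0, 0.25, ..., 2 years), two-sided
#' alpha 0.05, 80% power, 1:1 allocation, and treatment effects expressed as a
#' fractional slowing of the mean SARA slope (grid 20-50%).
#'
#' @param duration Trial duration in years.
#' @param interval Assessment interval in years.
#' @param alpha Two-sided type-I error.
#' @param power Target power.
#' @param effects Grid of fractional slope reductions in (0, 1).
#' @return A list of class `trial_design` with `visit_times` and the design
#'   parameters.
#' @export
trial_design <- function(duration = 2, interval = 0.25, alpha = 0.05,
                         power = 0.80, effects = seq(0.2, 0.5, by = 0.1)) {
  visit_times <- seq(0, duration, by = interval)
  stopifnot(length(visit_times) >= 2, visit_times[1] == 0,
            all(effects > 0 & effects < 1), alpha > 0, alpha < 1,
            power > 0, power < 1)
  structure(list(duration = duration, visit_times = visit_times,
                 alpha = alpha, power = power, effects = effects,
                 allocation = c(1, 1)),
            class = "trial_design")
}

#' Estimate slope variance components from longitudinal SARA data
#'
#' Random-slope LMM `sara ~ time + (time | subject)`; returns the mean slope
#' and the variance components entering the sample-size formula. Singular fits
#' fall back to independent random effects.
#'
#' @param data Data frame with `subject_id`, `time` (years), `sara`.
#' @return List of class `variance_components`: `mean_slope`, `slope_var`,
#'   `residual_var`, `intercept_var`, `n_subjects`.
#' @export
estimate_variance_components <- function(data) {
  df <- as.data.frame(data)
  stopifnot(all(c("subject_id", "time", "sara") %in% names(df)))
  df <- df[complete.cases(df[, c("subject_id", "time", "sara")]), ]
  nv <- table(df$subject_id)
  df <- df[df$subject_id %in% names(nv)[nv >= 2], ]  # longitudinal subset
  if (length(unique(df$subject_id)) < 5)
    stop("need >= 5 subjects with repeated SARA to estimate slope components")
  m <- suppressWarnings(suppressMessages(
    lme4::lmer(sara ~ time + (time | subject_id), data = df, REML = TRUE)))
  if (lme4::isSingular(m, tol = 1e-4)) {
    m <- suppressWarnings(suppressMessages(
      lme4::lmer(sara ~ time + (1 | subject_id) + (0 + time | subject_id),
                 data = df, REML = TRUE)))
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  slope_var <- vc$vcov[vc$var1 == "time" & is.na(vc$var2) &
                         vc$grp != "Residual"][1]
  int_var <- vc$vcov[vc$var1 == "(Intercept)" & is.na(vc$var2) &
                       vc$grp != "Residual"][1]
  res_var <- vc$vcov[vc$grp == "Residual"][1]
  structure(list(mean_slope = unname(lme4::fixef(m)["time"]),
                 slope_var = slope_var, residual_var = res_var,
                 intercept_var = int_var,
                 n_subjects = length(unique(df$subject_id)), model = m),
            class = "variance_components")
}

#' Build variance components directly
#'
#' @param mean_slope Mean outcome slope (units/year).
#' @param slope_var Between-subject slope variance.
#' @param residual_var Residual (within-visit) variance.
#' @param intercept_var Between-subject intercept variance (used by the
#'   simulation oracle, not by the closed-form formula).
#' @return A `variance_components` object.
#' @export
variance_components <- function(mean_slope, slope_var, residual_var,
                                intercept_var = 0) {
  stopifnot(slope_var >= 0, residual_var >= 0, intercept_var >= 0)
  structure(list(mean_slope = mean_slope, slope_var = slope_var,
                 residual_var = residual_var, intercept_var = intercept_var),
            class = "variance_components")
}

#' Closed-form sample size for detecting slowed slope progression
#'
#' Mixed-model-of-slopes formula: the variance of a subject's estimated slope
#' is `slope_var + residual_var / sum((t_j - mean(t))^2)`, and the per-arm
#' size for detecting a slope difference `delta = effect x mean_slope` at
#' two-sided alpha and the target power is
#' `n = ceiling(2 (z_{1-alpha/2} + z_{power})^2 sigma^2 / delta^2)`.
#'
#' @param vc A [variance_components()] object (mean_slope > 0).
#' @param design A [trial_design()].
#' @param effect Fractional slowing of the mean slope in (0, 1).
#' @return List with `n_per_arm`, `n_total`, `delta`, `slope_se_var` (the
#'   per-subject slope variance sigma^2), `sum_sq_time`.
#' @export
slope_sample_size <- function(vc, design, effect) {
  stopifnot(inherits(design, "trial_design"), effect > 0, effect < 1)
  if (!is.finite(vc$mean_slope) || vc$mean_slope <= 0)
    stop("mean slope must be positive to define a slowing effect")
  t <- design$visit_times
  sxx <- sum((t - mean(t))^2)
  delta <- effect * vc$mean_slope
  sigma2 <- vc$slope_var + vc$residual_var / sxx
  z <- qnorm(1 - design$alpha / 2) + qnorm(design$power)
  n_per_arm <- ceiling(2 * z^2 * sigma2 / delta^2)
  list(n_per_arm = n_per_arm, n_total = 2 * n_per_arm, delta = delta,
       slope_se_var = sigma2, sum_sq_time = sxx)
}

#' Monte-Carlo power of the slope trial
#'
#' Simulation oracle for [slope_sample_size()]: subjects per arm are simulated
#' with random intercepts, random slopes and residual noise at the design's
#' visit schedule, the treated arm's mean slope reduced by `effect`; each
#' replicate fits the treatment x time LMM and the empirical power is the
#' fraction of replicates rejecting at `alpha` (Wald test on the interaction).
#'
#' @param vc A [variance_components()] object.
#' @param design A [trial_design()].
#' @param effect Fractional slowing in (0, 1); `effect = 0` gives the null
#'   calibration.
#' @param n_per_arm Subjects per arm.
#' @param reps Simulation replicates (>= 200 recommended).
#' @param seed Integer seed.
#' @return List with `power`, `mc_se`, `n_nonconverged`, `reps`.
#' @export
monte_carlo_power <- function(vc, design, effect, n_per_arm, reps = 1000,
                              seed = 1L) {
  stopifnot(inherits(design, "trial_design"), n_per_arm >= 2, reps >= 1)
  t <- design$visit_times
  nv <- length(t)
  n <- 2 * n_per_arm
  trt <- rep(c(0, 1), each = n_per_arm)
  set.seed(seed)
  reject <- logical(reps)
  nonconv <- 0
  id <- factor(rep(seq_len(n), each = nv))
  time_l <- rep(t, times = n)
  trt_l <- rep(trt, each = nv)
  for (r in seq_len(reps)) {
    b0 <- rnorm(n, 0, sqrt(vc$intercept_var))
    b1 <- rnorm(n, vc$mean_slope * (1 - effect * trt), sqrt(vc$slope_var))
    y <- rep(b0, each = nv) + rep(b1, each = nv) * time_l +
      rnorm(n * nv, 0, sqrt(vc$residual_var))
    ok <- TRUE
    m <- withCallingHandlers(
      suppressMessages(lme4::lmer(y ~ trt_l * time_l + (time_l | id),
                                  REML = FALSE)),
      warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
    if (!ok) nonconv <- nonconv + 1
    cf <- summary(m)$coefficients
    zval <- cf["trt_l:time_l", "t value"]
    reject[r] <- 2 * pnorm(-abs(zval)) < design$alpha
  }
  p <- mean(reject)
  list(power = p, mc_se = sqrt(p * (1 - p) / reps),
       n_nonconverged = nonconv, reps = reps)
}

#' Stage cut-off enrichment sweep
#'
#' For each minimum-stage eligibility cut-off (optionally combined with age
#' and SARA windows), restricts the screened cohort, re-estimates the slope
#' variance components on the eligible subjects' longitudinal SARA, and
#' reports the required total sample size, its percentage reduction versus the
#' unenriched design, and the screen-failure rate (percent of the screened
#' baseline sample excluded). Cut-offs retaining fewer than `min_n` subjects
#' are dropped with a notice.
#'
#' @param baseline Data frame with one row per screened subject: `subject_id`,
#'   `stage`, and (for restriction) `age`, `sara`.
#' @param sara_long Longitudinal SARA table: `subject_id`, `time`, `sara`.
#' @param design A [trial_design()].
#' @param effect Fractional slowing used for the sample-size column.
#' @param cutoffs Integer vector of minimum-stage cut-offs.
#' @param restrict Optional list with `age = c(lo, hi)` and/or
#'   `sara = c(lo, hi)` eligibility windows applied at every cut-off.
#' @param reestimate Re-estimate variance components per cut-off subsample
#'   (default); `FALSE` keeps the full-sample components throughout.
#' @param min_n Minimum retained subjects for a modelled cut-off (default 15).
#' @return Data frame: `cutoff`, `n_retained`, `screen_failure_rate` (%),
#'   `n_required`, `sample_size_reduction` (%), `mean_slope`.
#' @export
enrichment_sweep <- function(baseline, sara_long, design, effect = 0.3,
                             cutoffs = 0:17, restrict = NULL,
                             reestimate = TRUE, min_n = 15) {
  bl <- as.data.frame(baseline)
  stopifnot(all(c("subject_id", "stage") %in% names(bl)))
  n_total <- nrow(bl)
  eligible_base <- rep(TRUE, n_total)
  if (!is.null(restrict$age))
    eligible_base <- eligible_base & bl$age >= restrict$age[1] &
      bl$age <= restrict$age[2]
  if (!is.null(restrict$sara))
    eligible_base <- eligible_base & bl$sara >= restrict$sara[1] &
      bl$sara <= restrict$sara[2]
  vc_full <- estimate_variance_components(
    sara_long[sara_long$subject_id %in% bl$subject_id, ])
  n0 <- slope_sample_size(vc_full, design, effect)$n_total
  rows <- list()
  for (j in sort(cutoffs)) {
    elig <- eligible_base & bl$stage >= j
    n_ret <- sum(elig)
    if (n_ret < min_n) {
      message("cut-off ", j, " retains ", n_ret, " < ", min_n,
              " subjects; not modelled")
      next
    }
    vc <- if (reestimate) {
      estimate_variance_components(
        sara_long[sara_long$subject_id %in% bl$subject_id[elig], ])
    } else {
      vc_full
    }
    nreq <- tryCatch(slope_sample_size(vc, design, effect)$n_total,
                     error = function(e) NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = j, n_retained = n_ret,
      screen_failure_rate = 100 * (n_total - n_ret) / n_total,
      n_required = nreq,
      sample_size_reduction = 100 * (1 - nreq / n0),
      mean_slope = vc$mean_slope)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
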