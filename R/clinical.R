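#' Estimate time from disease onset where unreported
#'
#' Rows with a reported gait-ataxia onset keep it; for the remainder a linear
#' model of onset age on expanded CAG repeat length, fitted on the reported
#' rows, predicts onset, and time from onset is current age minus predicted
#' onset (negative = pre-onset). Every row carries a provenance flag so
#' sensitivity analyses can exclude estimated values.
#'
#' @param clinical Data frame with `age`, `cag_expanded`, `onset_age` (NA where
#'   unreported) and optionally `onset_source`.
#' @return The table with `onset_age`, `time_from_onset` filled and
#'   `onset_source` in `{"reported", "estimated"}`; the onset model is attached
#'   as attribute `onset_model`.
#' @export
estimate_time_from_onset <- function(clinical) {
  df <- as.data.frame(clinical)
  stopifnot(all(c("age", "cag_expanded", "onset_age") %in% names(df)))
  rep_rows <- !is.na(df$onset_age)
  if (sum(rep_rows) < 10)
    stop("need >= 10 rows with reported onset to fit the CAG model, have ",
         sum(rep_rows))
  fit <- lm(onset_age ~ cag_expanded, data = df[rep_rows, ])
  fill <- !rep_rows & !is.na(df$cag_expanded) & !is.na(df$age)
  df$onset_source <- ifelse(rep_rows, "reported",
                            ifelse(fill, "estimated", NA_character_))
  df$onset_age[fill] <- predict(fit, newdata = df[fill, ])
  df$time_from_onset <- df$age - df$onset_age
  attr(df, "onset_model") <- fit
  df
}

#' ANCOVA of atrophy stage by gait status
#'
#' `stage ~ gait_status + age + sex` with an F-test for gait status (nested
#' model comparison) and all pairwise Tukey-adjusted contrasts of adjusted
#' means; FDR-adjusted p-values are reported alongside across the contrast
#' family.
#'
#' @param data Data frame with `stage`, `gait_status` (ordered levels normal <
#'   gait difficulties < walking aid < wheelchair), `age`, `sex`.
#' @param min_per_level Gait levels with fewer subjects are dropped with a
#'   notice (default 3).
#' @return List with `F`, `df`, `p`, `emmeans`, `contrasts` (estimate, Tukey p,
#'   FDR p), `n`, `dropped_levels`, `model`.
#' @export
stage_by_gait_ancova <- function(data, min_per_level = 3) {
  df <- as.data.frame(data)
  need <- c("stage", "gait_status", "age", "sex")
  stopifnot(all(need %in% names(df)))
  df <- df[complete.cases(df[, need]), ]
  levels_order <- c("normal", "gait difficulties", "walking aid", "wheelchair")
  df$gait_status <- factor(df$gait_status,
                           levels = intersect(levels_order,
                                              unique(df$gait_status)))
  counts <- table(df$gait_status)
  dropped <- names(counts)[counts < min_per_level]
  if (length(dropped)) {
    message("dropped gait level(s) with < ", min_per_level, " subjects: ",
            paste(dropped, collapse = ", "))
    df <- df[!df$gait_status %in% dropped, ]
    df$gait_status <- droplevels(df$gait_status)
  }
  if (nlevels(df$gait_status) < 2) stop("need >= 2 gait levels")
  full <- lm(stage ~ gait_status + age + sex, data = df)
  reduced <- lm(stage ~ age + sex, data = df)
  an <- anova(reduced, full)
  em <- emmeans::emmeans(full, ~gait_status)
  ctr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                               adjust = "tukey"))
  ctr$p_fdr <- p.adjust(ctr$p.value, method = "BH")
  list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]), p = an$`Pr(>F)`[2],
       emmeans = as.data.frame(summary(em)),
       contrasts = data.frame(contrast = ctr$contrast,
                              estimate = ctr$estimate, se = ctr$SE,
                              p_tukey = ctr$p.value, p_fdr = ctr$p_fdr,
                              stringsAsFactors = FALSE),
       n = nrow(df), dropped_levels = dropped, model = full)
}

std_beta <- function(formula, data, predictor) {
  # z-scale numeric outcome and predictors on the analysis sample, refit
  sdf <- data
  vars <- all.vars(formula)
  for (v in vars) {
    if (is.numeric(sdf[[v]]) && sd(sdf[[v]], na.rm = TRUE) > 0)
      sdf[[v]] <- as.numeric(scale(sdf[[v]]))
  }
  m <- lm(formula, data = sdf)
  cf <- summary(m)$coefficients
  if (!predictor %in% rownames(cf)) return(NA_real_)
  cf[predictor, 1]
}

#' Cross-sectional regressions of stage, SARA and INAS
#'
#' Mirrors the staged clinical analysis set: (a) atrophy stage on time from
#' onset with an ataxia-status interaction and per-group marginal trends;
#' (b) SARA on stage fitted in the whole sample and separately per ataxia
#' group (no group x stage interaction, avoiding endogenous stratification);
#' (c) INAS count on stage with an ataxia-status interaction. All models
#' adjust for age and sex; standardized coefficients come from refits with
#' z-scaled numeric variables; FDR adjustment is applied across the regression
#' family.
#'
#' @param data Data frame with `stage`, `time_from_onset`, `sara`, `inas`,
#'   `ataxia_status`, `age`, `sex`.
#' @param min_subset_n Results from subsets smaller than this are flagged
#'   `low_n` (default 10).
#' @return Data frame with one row per model term of interest: `model`,
#'   `term`, `b`, `beta`, `p`, `p_fdr`, `n`, `low_n`.
#' @export
stage_regressions <- function(data, min_subset_n = 10) {
  df <- as.data.frame(data)
  need <- c("stage", "age", "sex", "ataxia_status")
  stopifnot(all(need %in% names(df)))
  df$ataxia_status <- factor(df$ataxia_status,
                             levels = c("preataxic", "ataxic"))
  rows <- list()
  push <- function(model, term, b, beta, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, term = term, b = b, beta = beta, p = p, n = n,
      low_n = n < min_subset_n, stringsAsFactors = FALSE)
  }

  # (a) stage ~ time_from_onset, group differences probed via interaction
  if ("time_from_onset" %in% names(df)) {
    d <- df[complete.cases(df[, c("stage", "time_from_onset", need[-1])]), ]
    d$ataxia_status <- droplevels(d$ataxia_status)
    if (nrow(d) >= min_subset_n) {
      m_main <- lm(stage ~ time_from_onset + age + sex, data = d)
      cf_main <- summary(m_main)$coefficients
      push("stage_on_onset", "time_from_onset",
           cf_main["time_from_onset", 1],
           std_beta(stage ~ time_from_onset + age + sex, d,
                    "time_from_onset"),
           cf_main["time_from_onset", 4], nrow(d))
      if (nlevels(d$ataxia_status) >= 2) {
        m <- lm(stage ~ time_from_onset * ataxia_status + age + sex,
                data = d)
        cf <- summary(m)$coefficients
        itn <- "time_from_onset:ataxia_statusataxic"
        if (itn %in% rownames(cf))
          push("stage_on_onset", "time_from_onset:ataxic", cf[itn, 1],
               NA_real_, cf[itn, 4], nrow(d))
        tr <- emmeans::emtrends(m, ~ataxia_status, var = "time_from_onset")
        tr_sum <- as.data.frame(summary(tr, infer = c(TRUE, TRUE)))
        for (i in seq_len(nrow(tr_sum)))
          push("stage_on_onset",
               paste0("trend_", tr_sum$ataxia_status[i]),
               tr_sum$time_from_onset.trend[i], NA_real_, tr_sum$p.value[i],
               nrow(d))
      }
    }
  }

  # (b) SARA ~ stage + age + sex: whole sample and per group, never interacted
  if ("sara" %in% names(df)) {
    subsets <- list(whole = df,
                    preataxic = df[df$ataxia_status == "preataxic", ],
                    ataxic = df[df$ataxia_status == "ataxic", ])
    for (nm in names(subsets)) {
      d <- subsets[[nm]]
      d <- d[complete.cases(d[, c("sara", "stage", "age", "sex")]), ]
      if (nrow(d) < 4) next
      m <- lm(sara ~ stage + age + sex, data = d)
      cf <- summary(m)$coefficients
      push(paste0("sara_on_stage_", nm), "stage", cf["stage", 1],
           std_beta(sara ~ stage + age + sex, d, "stage"),
           cf["stage", 4], nrow(d))
    }
  }

  # (c) INAS ~ stage x ataxia_status + age + sex
  if ("inas" %in% names(df)) {
    d <- df[complete.cases(df[, c("inas", "stage", need[-1])]), ]
    d$ataxia_status <- droplevels(d$ataxia_status)
    if (nrow(d) >= min_subset_n) {
      m_main <- lm(inas ~ stage + age + sex, data = d)
      cf_main <- summary(m_main)$coefficients
      push("inas_on_stage", "stage", cf_main["stage", 1],
           std_beta(inas ~ stage + age + sex, d, "stage"),
           cf_main["stage", 4], nrow(d))
      if (nlevels(d$ataxia_status) >= 2) {
        m <- lm(inas ~ stage * ataxia_status + age + sex, data = d)
        cf <- summary(m)$coefficients
        itn <- "stage:ataxia_statusataxic"
        if (itn %in% rownames(cf))
          push("inas_on_stage", "stage:ataxic", cf[itn, 1], NA_real_,
               cf[itn, 4], nrow(d))
      }
    }
  }

  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
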