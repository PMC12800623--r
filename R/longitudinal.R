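#' Stage change over time via linear mixed models
#'
#' Fits `stage ~ time + (time | subject)` (participant-level random intercepts
#' and slopes; time in years from each subject's baseline scan) and reports the
#' fixed slope in stages/year with its 95% CI and p-value. With
#' `by_group = TRUE` a second model adds a time x ataxia-status interaction and
#' reports the estimated marginal linear trend per group. Singular
#' random-effect fits fall back to random intercepts only, flagged in the
#' result.
#'
#' @param table Data frame with `subject_id`, `time` (years), `stage`, and
#'   (for the group analysis) `ataxia_status` at baseline.
#' @param by_group Also fit the time x ataxia-status model.
#' @return List of class `stage_trend`: `slope`, `ci`, `p`, `singular_fallback`,
#'   `model`, and optionally `group_trends` (data.frame with per-group trend,
#'   CI, p).
#' @export
stage_change_model <- function(table, by_group = "ataxia_status" %in% names(table)) {
  df <- as.data.frame(table)
  stopifnot(all(c("subject_id", "time", "stage") %in% names(df)))
  # the trend is estimated on the longitudinal subset
  n_visits <- table(df$subject_id)
  df <- df[df$subject_id %in% names(n_visits)[n_visits >= 2], ]
  n_multi <- length(unique(df$subject_id))
  if (n_multi < 10) stop("need >= 2 visits for >= 10 subjects, have ", n_multi)

  fit_lmm <- function(formula_slope, formula_int) {
    m <- suppressWarnings(suppressMessages(
      lmerTest::lmer(formula_slope, data = df, REML = TRUE)))
    singular <- lme4::isSingular(m, tol = 1e-4)
    if (singular) {
      m <- suppressWarnings(suppressMessages(
        lmerTest::lmer(formula_int, data = df, REML = TRUE)))
    }
    list(model = m, singular_fallback = singular)
  }
  f <- fit_lmm(stage ~ time + (time | subject_id),
               stage ~ time + (1 | subject_id))
  sm <- summary(f$model)$coefficients
  ci <- suppressWarnings(confint(f$model, parm = "time", method = "Wald"))
  out <- list(slope = sm["time", "Estimate"], ci = as.numeric(ci["time", ]),
              p = sm["time", "Pr(>|t|)"],
              singular_fallback = f$singular_fallback, model = f$model)
  if (by_group) {
    g <- fit_lmm(stage ~ time * ataxia_status + (time | subject_id),
                 stage ~ time * ataxia_status + (1 | subject_id))
    tr <- emmeans::emtrends(g$model, ~ataxia_status, var = "time",
                            lmer.df = "satterthwaite")
    tr_sum <- as.data.frame(summary(tr, infer = c(TRUE, TRUE)))
    out$group_trends <- data.frame(
      ataxia_status = tr_sum$ataxia_status,
      trend = tr_sum$time.trend,
      ci_lower = tr_sum$lower.CL, ci_upper = tr_sum$upper.CL,
      p = tr_sum$p.value, stringsAsFactors = FALSE)
    out$group_model <- g$model
  }
  class(out) <- "stage_trend"
  out
}

#' @export
print.stage_trend <- function(x, ...) {
  cat(sprintf("Stage change: %.2f stages/year (95%% CI %.2f to %.2f, p = %.2g)%s\n",
              x$slope, x$ci[1], x$ci[2], x$p,
              if (x$singular_fallback) " [random-intercept fallback]" else ""))
  if (!is.null(x$group_trends)) print(x$group_trends)
  invisible(x)
}

#' Stage monotonicity audit
#'
#' Tabulates the stage difference between consecutive scans of each subject:
#' increases, no change, and decreases (the latter violate the model's
#' monotone-progression assumption), with a magnitude breakdown and optional
#' stratification by baseline ataxia status.
#'
#' @param table Data frame with `subject_id`, `time`, `stage`, optionally
#'   `ataxia_status`.
#' @return List with `pairs` (per consecutive-scan-pair deltas), `overall`
#'   (counts/proportions of increase/no change/decrease), `magnitude`
#'   (table of decrease magnitudes), and `by_status` when available.
#' @export
monotonicity_report <- function(table) {
  df <- as.data.frame(table)
  stopifnot(all(c("subject_id", "time", "stage") %in% names(df)))
  pairs <- do.call(rbind, lapply(split(df, df$subject_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    if (is.unsorted(s$time, strictly = TRUE)) {
      s <- s[order(s$time), ]
      if (anyDuplicated(s$time)) stop("unordered or duplicated visit times for ",
                                      s$subject_id[1])
    }
    data.frame(subject_id = s$subject_id[-1],
               time = s$time[-1],
               delta = diff(s$stage),
               ataxia_status = if ("ataxia_status" %in% names(s))
                 s$ataxia_status[1] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) stop("no follow-up scan pairs")
  rownames(pairs) <- NULL
  summarize <- function(d) {
    n <- length(d)
    data.frame(n_pairs = n,
               n_increase = sum(d > 0), prop_increase = mean(d > 0),
               n_unchanged = sum(d == 0), prop_unchanged = mean(d == 0),
               n_decrease = sum(d < 0), prop_decrease = mean(d < 0))
  }
  out <- list(pairs = pairs, overall = summarize(pairs$delta),
              magnitude = table(decrease = -pairs$delta[pairs$delta < 0]))
  if (!all(is.na(pairs$ataxia_status))) {
    by_status <- do.call(rbind, lapply(split(pairs, pairs$ataxia_status),
                                       function(s) summarize(s$delta)))
    by_status <- cbind(ataxia_status = rownames(by_status), by_status)
    rownames(by_status) <- NULL
    out$by_status <- by_status
  }
  out
}

#' Scanner effects on atrophy stage
#'
#' Multiple regression of stage on scanner manufacturer and field strength,
#' with time from disease onset as a covariate (sites tend to contribute cases
#' at different disease stages). Single-level factors are dropped with a
#' notice.
#'
#' @param table Data frame with `stage`, `scanner_manufacturer`,
#'   `field_strength`, `time_from_onset`.
#' @return List with `coefficients` (term, estimate, CI, p), `dropped`
#'   (single-level predictors removed), and the `model`.
#' @export
scanner_effect_check <- function(table) {
  df <- as.data.frame(table)
  need <- c("stage", "scanner_manufacturer", "field_strength",
            "time_from_onset")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[complete.cases(df[, need]), ]
  terms <- c()
  dropped <- c()
  for (v in c("scanner_manufacturer", "field_strength")) {
    if (length(unique(df[[v]])) >= 2) {
      df[[v]] <- factor(df[[v]])
      terms <- c(terms, v)
    } else {
      dropped <- c(dropped, v)
    }
  }
  if (length(dropped))
    message("dropped single-level predictor(s): ", paste(dropped, collapse = ", "))
  fml <- as.formula(paste("stage ~", paste(c(terms, "time_from_onset"),
                                           collapse = " + ")))
  m <- lm(fml, data = df)
  cf <- summary(m)$coefficients
  ci <- confint(m)
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      ci_lower = ci[, 1], ci_upper = ci[, 2], p = cf[, 4],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  list(coefficients = coefs, dropped = dropped, model = m, n = nrow(df))
}
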