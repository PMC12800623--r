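#' Fit the normative model for w-scoring
#'
#' With healthy controls as the reference population, each regional volume is
#' residualized in two sequential steps: (1) ordinary least squares of the raw
#' volume on intracranial volume (ICV); (2) least squares of the stage-1
#' residual on age and sex. The SD of the stage-2 residuals defines the w-score
#' unit for that region. By construction the fitting controls have mean w = 0
#' and SD = 1 in every region.
#'
#' A single joint regression (volume ~ ICV + age + sex) is available via
#' `joint = TRUE`; the sequential form is the default.
#'
#' @param controls A volume table (see [read_volume_table()]) restricted to, or
#'   containing, control rows; only rows with `group == "control"` are used.
#' @param regions Region column names (default [sca3_regions()]).
#' @param baseline_only If `TRUE` (default) only `visit_index == 1` rows enter
#'   the fit, so longitudinal controls are not over-weighted.
#' @param joint Use one joint regression instead of sequential residualization.
#' @return An object of class `normative_model` with per-region coefficients
#'   and `residual_sd`.
#' @export
fit_normative_model <- function(controls, regions = sca3_regions(),
                                baseline_only = TRUE, joint = FALSE) {
  df <- as.data.frame(controls)
  if ("group" %in% names(df)) df <- df[df$group == "control", , drop = FALSE]
  if (baseline_only && "visit_index" %in% names(df))
    df <- df[df$visit_index == 1, , drop = FALSE]
  need <- c("age", "sex", "icv", regions)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("control table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[complete.cases(df[, need]), , drop = FALSE]
  if (nrow(df) < 20) stop("need >= 20 complete control visits, have ", nrow(df))
  if (length(unique(df$sex)) < 2)
    stop("controls include a single sex; normative design is singular")
  male <- as.numeric(df$sex == "male")
  fits <- lapply(regions, function(r) {
    v <- df[[r]]
    if (joint) {
      f <- lm(v ~ icv + age + male, data = data.frame(v = v, icv = df$icv,
                                                      age = df$age, male = male))
      if (anyNA(coef(f))) stop("singular normative design for region ", r)
      rsd <- sd(resid(f))
      if (rsd <= .Machine$double.eps * max(abs(v)))
        stop("degenerate (constant) volumes for region ", r)
      list(joint = TRUE, coef = coef(f), residual_sd = rsd)
    } else {
      f1 <- lm(v ~ icv, data = data.frame(v = v, icv = df$icv))
      if (anyNA(coef(f1))) stop("singular ICV regression for region ", r)
      r1 <- resid(f1)
      f2 <- lm(r1 ~ age + male, data = data.frame(r1 = r1, age = df$age,
                                                  male = male))
      if (anyNA(coef(f2))) stop("singular age/sex regression for region ", r)
      rsd <- sd(resid(f2))
      if (rsd <= .Machine$double.eps * max(abs(v)))
        stop("degenerate (constant) volumes for region ", r)
      list(joint = FALSE, icv_coefficients = coef(f1),
           adjustment_coefficients = coef(f2), residual_sd = rsd)
    }
  })
  names(fits) <- regions
  structure(list(regions = regions, fits = fits, joint = joint,
                 n_controls = nrow(df)),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative w-score model: %d regions, %d control visits (%s)\n",
              length(x$regions), x$n_controls,
              if (x$joint) "joint" else "sequential residualization"))
  invisible(x)
}

#' Compute w-scores
#'
#' Applies a fitted normative model identically to controls and patients:
#' w = (stage-2 residual) / residual SD, in control SD units. Negative w means
#' atrophy; the severity used by the progression model is z = -w. Rows with a
#' missing covariate or volume yield `NA` w-scores (never imputed).
#'
#' @param model A [fit_normative_model()] fit.
#' @param table A volume table containing `age`, `sex`, `icv` and the model's
#'   region columns.
#' @return A data.frame with `subject_id`, `visit_index` (when present in
#'   `table`) and one w-score column per region, class `wscore_matrix`.
#' @export
compute_wscores <- function(model, table) {
  df <- as.data.frame(table)
  miss <- setdiff(c("age", "sex", "icv", model$regions), names(df))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  male <- as.numeric(df$sex == "male")
  W <- matrix(NA_real_, nrow(df), length(model$regions),
              dimnames = list(NULL, model$regions))
  for (r in model$regions) {
    fit <- model$fits[[r]]
    v <- df[[r]]
    if (fit$joint) {
      mu <- fit$coef[1] + fit$coef["icv"] * df$icv + fit$coef["age"] * df$age +
        fit$coef["male"] * male
      W[, r] <- (v - mu) / fit$residual_sd
    } else {
      r1 <- v - (fit$icv_coefficients[1] + fit$icv_coefficients["icv"] * df$icv)
      r2 <- r1 - (fit$adjustment_coefficients[1] +
                    fit$adjustment_coefficients["age"] * df$age +
                    fit$adjustment_coefficients["male"] * male)
      W[, r] <- r2 / fit$residual_sd
    }
  }
  id_cols <- intersect(c("subject_id", "visit_index", "group"), names(df))
  out <- cbind(df[, id_cols, drop = FALSE], as.data.frame(W))
  class(out) <- c("wscore_matrix", "data.frame")
  out
}

#' Severity matrix from w-scores
#'
#' The progression model works on severities z = -w (volume loss positive).
#'
#' @param wscores A [compute_wscores()] result (or data.frame with region
#'   columns).
#' @param regions Region columns (default [sca3_regions()]).
#' @return Numeric matrix visits x regions of severities.
#' @export
severity_matrix <- function(wscores, regions = sca3_regions()) {
  df <- as.data.frame(wscores)
  miss <- setdiff(regions, names(df))
  if (length(miss)) stop("w-score table lacks region(s): ",
                         paste(miss, collapse = ", "))
  -as.matrix(df[, regions, drop = FALSE])
}

#' Two-sample Welch t-test from summary statistics
#'
#' Welch's unequal-variance t statistic and Satterthwaite degrees of freedom
#' computed from group means, SDs and sizes, as needed to reproduce group
#' comparisons from printed cohort tables.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t` (group 2 minus group 1), `df`, and two-sided `p`.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 > 1, n2 > 1)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
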