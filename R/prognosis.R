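#' Candidate prognostic model specifications
#'
#' The clinical reference model predicts longitudinal SARA from baseline age,
#' sex, CAG repeat length, INAS count and gait status, each interacted with
#' continuous time, with per-subject random intercepts and time slopes. MRI
#' variants add one readout x time term each: atrophy stage, each single
#' region's w-score, all region w-scores jointly, or the global ROI readout
#' (sum of the w-scores). With B biomarkers this yields B + 4 specs.
#'
#' @param biomarkers Character vector of region names (>= 1).
#' @return List of specs (label, readout columns, flags), class
#'   `prognosis_specs`.
#' @export
build_model_set <- function(biomarkers = sca3_regions()) {
  if (length(biomarkers) < 1) stop("need at least one biomarker")
  if (anyDuplicated(biomarkers)) stop("duplicate biomarker labels")
  specs <- list(list(label = "reference", readouts = character(0),
                     flag = NA_character_),
                list(label = "stage", readouts = "stage0",
                     flag = NA_character_))
  for (b in biomarkers)
    specs <- c(specs, list(list(label = b, readouts = paste0("w_", b),
                                flag = NA_character_)))
  specs <- c(specs,
             list(list(label = "all_volumes",
                       readouts = paste0("w_", biomarkers),
                       flag = if (length(biomarkers) == 1)
                         "collapses to single volume" else NA_character_),
                  list(label = "global_roi", readouts = "w_global",
                       flag = if (length(biomarkers) == 1)
                         "collapses to single volume" else NA_character_)))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate spec labels")
  structure(specs, class = "prognosis_specs")
}

spec_formula <- function(spec) {
  base <- c("age0", "sex", "cag0", "inas0", "gait0")
  rhs <- paste(sprintf("%s * time", c(base, spec$readouts)), collapse = " + ")
  as.formula(paste("sara ~", rhs, "+ (time | subject_id)"))
}

#' Assemble the longitudinal SARA analysis table
#'
#' One row per SARA assessment with baseline predictors attached: baseline
#' age, sex, CAG, INAS, gait status (coded ordinally 0-3), baseline atrophy
#' stage, and baseline w-scores per region plus their sum (`w_global`).
#' Numeric predictors are z-scored relative to the baseline observations;
#' scaling constants are stored as an attribute so coefficients can be
#' unstandardized.
#'
#' @param clinical Per-visit clinical table (`subject_id`, `visit_index`,
#'   `time`, `sara`, baseline covariates at `visit_index == 1`).
#' @param stages Baseline stage per subject: data.frame `subject_id`, `stage`.
#' @param wscores Baseline w-scores (see [compute_wscores()]).
#' @param regions Region columns (default [sca3_regions()]).
#' @return Data frame ready for [fit_and_compare_aic()] /
#'   [cv_rmse_max_followup()], with attribute `scaling`.
#' @export
prognosis_data <- function(clinical, stages, wscores,
                           regions = sca3_regions()) {
  cl <- as.data.frame(clinical)
  base <- cl[cl$visit_index == 1, ]
  gait_levels <- c("normal", "gait difficulties", "walking aid", "wheelchair")
  base$gait0 <- as.numeric(factor(base$gait_status, levels = gait_levels)) - 1
  bl <- data.frame(subject_id = base$subject_id, age0 = base$age,
                   sex = base$sex, cag0 = base$cag_expanded,
                   inas0 = base$inas, gait0 = base$gait0,
                   stringsAsFactors = FALSE)
  st <- as.data.frame(stages)
  names(st)[names(st) == "map_stage"] <- "stage"
  bl <- merge(bl, st[, c("subject_id", "stage")], by = "subject_id")
  names(bl)[names(bl) == "stage"] <- "stage0"
  ws <- as.data.frame(wscores)
  ws <- ws[ws$visit_index == 1, c("subject_id", regions)]
  names(ws)[-1] <- paste0("w_", regions)
  ws$w_global <- rowSums(ws[, -1, drop = FALSE])
  bl <- merge(bl, ws, by = "subject_id")

  long <- merge(cl[, c("subject_id", "visit_index", "time", "sara")], bl,
                by = "subject_id")
  long <- long[complete.cases(long), ]
  # random slopes are only identifiable on the longitudinal subset
  nv <- table(long$subject_id)
  long <- long[long$subject_id %in% names(nv)[nv >= 2], ]
  num <- c("age0", "cag0", "inas0", "gait0", "stage0",
           paste0("w_", regions), "w_global")
  scaling <- list()
  base_rows <- long$visit_index == 1
  for (v in num) {
    mu <- mean(long[[v]][base_rows])
    sdv <- sd(long[[v]][base_rows])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    scaling[[v]] <- c(mean = mu, sd = sdv)
    long[[v]] <- (long[[v]] - mu) / sdv
  }
  long <- long[order(long$subject_id, long$time), ]
  rownames(long) <- NULL
  attr(long, "scaling") <- scaling
  long
}

fit_spec <- function(spec, data, reml = FALSE) {
  ok <- TRUE
  m <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(spec_formula(spec), data = data,
                                    REML = reml)),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  list(model = m, converged = ok)
}

#' Compare prognostic models by AIC
#'
#' Maximum-likelihood (not REML) fits of every spec so AICs are comparable
#' across fixed-effect structures; reports AIC, delta AIC versus the clinical
#' reference, and the readout x time coefficients with p-values (the primary
#' prognostic test per readout).
#'
#' @param specs A [build_model_set()] list.
#' @param data A [prognosis_data()] table.
#' @return List with `table` (label, AIC, delta_aic, converged, flag),
#'   `readout_effects` (label, term, beta, p), and `models`.
#' @export
fit_and_compare_aic <- function(specs, data) {
  fits <- lapply(specs, fit_spec, data = data, reml = FALSE)
  labels <- vapply(specs, `[[`, character(1), "label")
  aic <- vapply(fits, function(f) AIC(f$model), numeric(1))
  conv <- vapply(fits, `[[`, logical(1), "converged")
  ref <- which(labels == "reference")
  if (!length(ref)) stop("spec set lacks the clinical reference model")
  tab <- data.frame(label = labels, aic = aic, delta_aic = aic - aic[ref],
                    converged = conv,
                    flag = vapply(specs, `[[`, character(1), "flag"),
                    stringsAsFactors = FALSE)
  effects <- list()
  for (i in seq_along(specs)) {
    for (r in specs[[i]]$readouts) {
      cf <- summary(fits[[i]]$model)$coefficients
      term <- intersect(c(paste0(r, ":time"), paste0("time:", r)),
                        rownames(cf))
      if (length(term)) {
        effects[[length(effects) + 1L]] <- data.frame(
          label = labels[i], term = term[1], beta = cf[term[1], "Estimate"],
          p = cf[term[1], "Pr(>|t|)"], stringsAsFactors = FALSE)
      }
    }
  }
  list(table = tab,
       readout_effects = if (length(effects)) do.call(rbind, effects) else NULL,
       models = setNames(lapply(fits, `[[`, "model"), labels))
}

#' Cross-validated prediction error at the last follow-up
#'
#' Repeated subject-level cross-validation: per repeat and fold, each spec is
#' fitted on the training subjects and SARA at each test subject's final
#' available follow-up is predicted from baseline covariates alone (fixed
#' effects only; random effects are unobservable for new subjects). Reports
#' the pooled RMSE per spec on the raw SARA scale, the per-fold RMSE matrix
#' (for corrected resampled tests), and a per-visit RMSE breakdown.
#'
#' @param specs A [build_model_set()] list.
#' @param data A [prognosis_data()] table.
#' @param repeats,folds Cross-validation design (default 10 x 10).
#' @param seed Integer seed for the fold assignments.
#' @return List with `rmse` (per spec), `fold_rmse` (J x specs matrix,
#'   J = repeats x folds), `by_visit`, `n_train`, `n_test`, `n_skipped`,
#'   `n_nonconverged`.
#' @export
cv_rmse_max_followup <- function(specs, data, repeats = 10, folds = 10,
                                 seed = 1L) {
  labels <- vapply(specs, `[[`, character(1), "label")
  subjects <- unique(data$subject_id)
  has_fu <- tapply(data$time, data$subject_id, function(t) any(t > 0))
  set.seed(seed)
  J <- repeats * folds
  fold_rmse <- matrix(NA_real_, J, length(specs),
                      dimnames = list(NULL, labels))
  errors <- vector("list", length(specs))
  visit_of_err <- vector("list", length(specs))
  n_skipped <- 0
  n_nonconv <- 0
  row <- 0
  for (r in seq_len(repeats)) {
    fold_id <- setNames(sample(rep_len(seq_len(folds), length(subjects))),
                        subjects)
    for (f in seq_len(folds)) {
      row <- row + 1
      test_ids <- subjects[fold_id[subjects] == f]
      skip <- !has_fu[test_ids]
      n_skipped <- n_skipped + sum(skip)
      test_ids <- test_ids[!skip]
      if (!length(test_ids)) next
      train <- data[!data$subject_id %in% test_ids, ]
      # last available follow-up per test subject
      test <- do.call(rbind, lapply(test_ids, function(id) {
        s <- data[data$subject_id == id & data$time > 0, ]
        s[which.max(s$time), ]
      }))
      for (i in seq_along(specs)) {
        fit <- tryCatch(fit_spec(specs[[i]], train, reml = FALSE),
                        error = function(e) NULL)
        if (is.null(fit)) { n_nonconv <- n_nonconv + 1; next }
        if (!fit$converged) n_nonconv <- n_nonconv + 1
        pred <- predict(fit$model, newdata = test, re.form = NA)
        err <- test$sara - pred
        fold_rmse[row, i] <- sqrt(mean(err^2))
        errors[[i]] <- c(errors[[i]], err)
        visit_of_err[[i]] <- c(visit_of_err[[i]], test$visit_index)
      }
    }
  }
  rmse <- vapply(errors, function(e)
    if (length(e)) sqrt(mean(e^2)) else NA_real_, numeric(1))
  by_visit <- lapply(seq_along(specs), function(i) {
    if (!length(errors[[i]])) return(NULL)
    sp <- split(errors[[i]], visit_of_err[[i]])
    data.frame(label = labels[i], visit_index = as.integer(names(sp)),
               rmse = vapply(sp, function(e) sqrt(mean(e^2)), numeric(1)),
               n = lengths(sp), stringsAsFactors = FALSE)
  })
  n_test <- length(subjects) / folds
  list(rmse = setNames(rmse, labels), fold_rmse = fold_rmse,
       by_visit = do.call(rbind, by_visit),
       n_train = length(subjects) - n_test, n_test = n_test,
       n_skipped = n_skipped, n_nonconverged = n_nonconv)
}

#' Nadeau-Bengio corrected resampled t-test
#'
#' t-test on J = repeats x folds cross-validated performance differences with
#' the variance inflated by the train/test overlap factor:
#' `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))`, df = J - 1. The
#' naive resampled t-test (factor 1/J only) is anti-conservative because fold
#' results share training data.
#'
#' @param d Vector of per-fold performance differences.
#' @param n_train,n_test Training and test set sizes per fold.
#' @return List with `t`, `df`, `p`, and the naive `t_naive`, `p_naive`.
#' @export
nadeau_bengio_test <- function(d, n_train, n_test) {
  d <- d[is.finite(d)]
  J <- length(d)
  if (J < 2) stop("need at least 2 fold differences")
  v <- var(d)
  if (v == 0) {
    t_val <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    t_naive <- t_val
  } else {
    t_val <- mean(d) / sqrt((1 / J + n_test / n_train) * v)
    t_naive <- mean(d) / sqrt(v / J)
  }
  list(t = t_val, df = J - 1, p = 2 * pt(-abs(t_val), J - 1),
       t_naive = t_naive, p_naive = 2 * pt(-abs(t_naive), J - 1))
}

#' Compare cross-validated RMSEs against the clinical reference
#'
#' Applies [nadeau_bengio_test()] to each spec's fold-level RMSE differences
#' versus the reference model, with FDR adjustment across the model family.
#'
#' @param cv A [cv_rmse_max_followup()] result.
#' @param reference Label of the reference spec.
#' @return Data frame: label, rmse, delta_rmse, t, p, p_fdr.
#' @export
compare_rmse <- function(cv, reference = "reference") {
  labels <- colnames(cv$fold_rmse)
  if (!reference %in% labels) stop("no spec labelled '", reference, "'")
  out <- list()
  for (l in setdiff(labels, reference)) {
    d <- cv$fold_rmse[, l] - cv$fold_rmse[, reference]
    nb <- nadeau_bengio_test(d, cv$n_train, cv$n_test)
    out[[l]] <- data.frame(label = l, rmse = cv$rmse[l],
                           delta_rmse = cv$rmse[l] - cv$rmse[reference],
                           t = nb$t, p = nb$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
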