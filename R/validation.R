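#' Positional density of MCMC sequence samples
#'
#' The events x positions matrix underlying positional variance diagrams:
#' entry (e, p) is the fraction of samples placing event e at position p.
#'
#' @param samples Matrix of sequences (rows = samples, columns = positions,
#'   entries = event indices), as returned by [fit_single_sequence()].
#' @param events An [ebm_events()] object.
#' @return Matrix events x positions; rows sum to 1.
#' @export
positional_density <- function(samples, events) {
  samples <- as.matrix(samples)
  N <- events$n_events
  if (ncol(samples) != N) stop("sample width does not match the event set")
  if (nrow(samples) == 0) stop("no samples")
  if (!all(samples %in% seq_len(N))) stop("samples contain unknown event ids")
  D <- matrix(0, N, N, dimnames = list(events$table$label, seq_len(N)))
  for (p in seq_len(N)) {
    tab <- tabulate(samples[, p], nbins = N)
    D[, p] <- D[, p] + tab
  }
  D / nrow(samples)
}

#' Mean Bhattacharyya coefficient between two positional densities
#'
#' Per event, BC = sum over positions of sqrt(p * q); the mean over events
#' summarises how similarly two fitted models locate the events. 1 means
#' identical densities, 0 disjoint support.
#'
#' @param d1,d2 Positional density matrices over the same event set.
#' @return Mean Bhattacharyya coefficient in `[0, 1]`.
#' @export
bhattacharyya_mean <- function(d1, d2) {
  if (!all(dim(d1) == dim(d2))) stop("positional density shape mismatch")
  mean(rowSums(sqrt(d1 * d2)))
}

#' Fold-wise sequence similarity under cross-validation
#'
#' Trains one model per training split and computes the mean Bhattacharyya
#' coefficient for every unordered pair of fold positional densities, the
#' robustness metric for the fitted atrophy sequence.
#'
#' @inheritParams fit_single_sequence
#' @param folds Number of cross-validation folds (>= 2).
#' @return List with `bc_mean`, `bc_sd`, `pairs` (per-pair BC values), and
#'   `fold_models`.
#' @export
cross_validated_similarity <- function(z, events, folds = 10,
                                       control = ebm_control(profile = "test"),
                                       seed = 1L) {
  z <- prepare_severities(z, events)
  stopifnot(folds >= 2)
  if (control$n_mcmc <= 0) stop("fold similarity needs MCMC samples")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(z)))
  fits <- vector("list", folds)
  dens <- vector("list", folds)
  for (f in seq_len(folds)) {
    fit <- tryCatch(
      fit_single_sequence(z[fold_id != f, , drop = FALSE], events, control,
                          seed = seed + f),
      error = function(e) stop("fold ", f, " training failed: ",
                               conditionMessage(e)))
    fits[[f]] <- fit
    dens[[f]] <- positional_density(fit$samples, events)
  }
  pairs <- utils::combn(folds, 2)
  bc <- apply(pairs, 2, function(ix)
    bhattacharyya_mean(dens[[ix[1]]], dens[[ix[2]]]))
  list(bc_mean = mean(bc), bc_sd = sd(bc), pairs = bc, fold_models = fits,
       fold_densities = dens)
}

#' Randomised-sequence Bhattacharyya baseline
#'
#' The null reference for fold similarity: pairs of positional densities built
#' from uniformly drawn valid sequences (respecting within-biomarker threshold
#' ordering by default), scored with [bhattacharyya_mean()]. By default each
#' density is the one-hot density of a single random sequence — the overlap
#' expected when two models share no ordering information. `n_per_density > 1`
#' smooths each density over a bundle of random sequences, which raises the
#' baseline towards 1 as the bundles approach the uniform positional marginal.
#'
#' @param events An [ebm_events()] object.
#' @param n_draws Number of density pairs (>= 2).
#' @param n_per_density Sequences per density (default 1, one-hot).
#' @param constrained If `FALSE`, draw unconstrained permutations instead.
#' @param seed Integer seed.
#' @return List with `bc_mean`, `bc_sd`, and the per-pair values `bc`.
#' @export
random_sequence_baseline <- function(events, n_draws = 100,
                                     n_per_density = 1, constrained = TRUE,
                                     seed = 1L) {
  stopifnot(n_draws >= 2, n_per_density >= 1)
  set.seed(seed)
  N <- events$n_events
  draw_density <- function() {
    S <- do.call(rbind, lapply(seq_len(n_per_density), function(i)
      if (constrained) random_sequence(events) else sample.int(N)))
    positional_density(S, events)
  }
  bc <- vapply(seq_len(n_draws), function(i)
    bhattacharyya_mean(draw_density(), draw_density()), numeric(1))
  list(bc_mean = mean(bc), bc_sd = sd(bc), bc = bc)
}

#' Out-of-sample staging agreement
#'
#' Each visit is staged twice: by the model trained on all data and by the
#' model trained without the visit's fold. Reports the mean absolute stage
#' error (with SD) and a Bland-Altman analysis (mean difference, 1.96 SD
#' limits of agreement, and the proportional-bias regression of difference on
#' mean).
#'
#' @inheritParams cross_validated_similarity
#' @param full_model Optional pre-fitted full-sample model (saves refitting).
#' @return List with `stage_full`, `stage_oos`, `mae`, `mae_sd`,
#'   `bland_altman` (mean_diff, loa, slope, slope_p).
#' @export
out_of_sample_staging <- function(z, events, folds = 10,
                                  control = ebm_control(profile = "test"),
                                  seed = 1L, full_model = NULL) {
  z <- prepare_severities(z, events)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(z)))
  if (is.null(full_model))
    full_model <- fit_subtypes(z, events, k = 1, control = control, seed = seed)
  stage_full <- assign_stages(full_model, z)$map_stage
  stage_oos <- rep(NA_integer_, nrow(z))
  oos_control <- control
  oos_control$n_mcmc <- 0L  # only the ML sequence is needed per fold
  for (f in seq_len(folds)) {
    m <- fit_subtypes(z[fold_id != f, , drop = FALSE], events, k = 1,
                      control = oos_control, seed = seed + f)
    stage_oos[fold_id == f] <-
      assign_stages(m, z[fold_id == f, , drop = FALSE])$map_stage
  }
  err <- abs(stage_oos - stage_full)
  d <- stage_oos - stage_full
  m <- (stage_oos + stage_full) / 2
  slope <- NA_real_
  slope_p <- NA_real_
  if (sd(m) > 0) {
    ba_fit <- lm(d ~ m)
    slope <- coef(ba_fit)[["m"]]
    slope_p <- summary(ba_fit)$coefficients["m", 4]
  }
  list(stage_full = stage_full, stage_oos = stage_oos,
       mae = mean(err), mae_sd = sd(err),
       bland_altman = list(mean_diff = mean(d),
                           loa = mean(d) + c(-1.96, 1.96) * sd(d),
                           slope = slope, slope_p = slope_p))
}
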