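#' Fitting settings for the event-based model
#'
#' Defaults follow common practice for z-score event-based models: `sigma = 1`
#' because the data are w-scored (so severities are in control SD units) and a
#' trajectory ceiling `z_max = 5`. The stage prior is uniform over stages
#' 0..N unless given. The `full` profile (25 greedy starts, 1e5 MCMC samples
#' after 1e4 burn-in) matches production use; the `test` profile is a reduced
#' configuration for desk-scale runs.
#'
#' @param n_starts Number of random greedy starts.
#' @param n_mcmc Number of post-burn-in MCMC samples (0 = greedy only).
#' @param burn_in Burn-in iterations discarded before sampling.
#' @param sigma Likelihood SD in severity (z) units.
#' @param z_max Severity at the end of the sequence for the trajectory ceiling.
#' @param stage_prior Optional probability vector over stages 0..N.
#' @param max_em_iter,em_tol EM settings for subtype fitting.
#' @param n_bipartitions Random bipartitions tried when splitting a cluster.
#' @param profile Shortcut: `"full"` or `"test"` presets for
#'   `n_starts`/`n_mcmc`/`burn_in` (explicit arguments win).
#' @return A list of settings of class `ebm_control`.
#' @export
ebm_control <- function(n_starts = NULL, n_mcmc = NULL, burn_in = NULL,
                        sigma = 1, z_max = 5, stage_prior = NULL,
                        max_em_iter = 15, em_tol = 1e-4, n_bipartitions = 3,
                        profile = c("full", "test")) {
  profile <- match.arg(profile)
  preset <- switch(profile,
                   full = list(n_starts = 25L, n_mcmc = 100000L, burn_in = 10000L),
                   test = list(n_starts = 5L, n_mcmc = 10000L, burn_in = 1000L))
  ctl <- list(
    n_starts = as.integer(n_starts %||% preset$n_starts),
    n_mcmc = as.integer(n_mcmc %||% preset$n_mcmc),
    burn_in = as.integer(burn_in %||% preset$burn_in),
    sigma = sigma, z_max = z_max, stage_prior = stage_prior,
    max_em_iter = max_em_iter, em_tol = em_tol,
    n_bipartitions = n_bipartitions, profile = profile
  )
  stopifnot(ctl$sigma > 0, ctl$z_max > 0, ctl$n_starts >= 1,
            ctl$n_mcmc >= 0, ctl$burn_in >= 0)
  class(ctl) <- "ebm_control"
  ctl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage_prior <- function(events, control) {
  N <- events$n_events
  p <- control$stage_prior %||% rep(1 / (N + 1), N + 1)
  stopifnot(length(p) == N + 1, all(p >= 0), sum(p) > 0)
  log(p / sum(p))
}

# validate/prepare a severity matrix; drops all-missing rows with a warning
prepare_severities <- function(z, events) {
  z <- as.matrix(z)
  if (is.null(colnames(z))) {
    stopifnot(ncol(z) == length(events$biomarkers))
    colnames(z) <- events$biomarkers
  }
  missing <- setdiff(events$biomarkers, colnames(z))
  if (length(missing)) stop("severity matrix lacks biomarker(s): ",
                            paste(missing, collapse = ", "))
  z <- z[, events$biomarkers, drop = FALSE]
  all_na <- rowSums(!is.na(z)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " visit(s) with all biomarkers missing excluded")
    z <- z[!all_na, , drop = FALSE]
  }
  storage.mode(z) <- "double"
  z
}

#' Expected severity trajectory of a biomarker along a sequence
#'
#' Piecewise-linear interpolation through (0, 0), the biomarker's event
#' positions at their threshold severities, and (N, z_max) when its last event
#' lies before the end of the sequence (constant afterwards otherwise).
#'
#' @param sequence Integer event-index sequence.
#' @param events An [ebm_events()] object.
#' @param biomarker Biomarker name (default: all).
#' @param stage Stages at which to evaluate, integers in 0..N (default all).
#' @param z_max Severity ceiling (default 5).
#' @return Numeric matrix `length(stage)` x biomarkers of expected severities.
#' @export
expected_trajectory <- function(sequence, events, biomarker = NULL,
                                stage = NULL, z_max = 5) {
  N <- events$n_events
  stage <- stage %||% 0:N
  if (any(stage < 0 | stage > N)) stop("stage outside 0..", N)
  stopifnot(is_valid_sequence(sequence, events))
  G <- ebm_trajectory_cpp(as.integer(sequence) - 1L, event_bio0(events),
                          events$table$threshold, length(events$biomarkers),
                          z_max)
  colnames(G) <- events$biomarkers
  keep <- biomarker %||% events$biomarkers
  out <- G[stage + 1L, keep, drop = FALSE]
  rownames(out) <- stage
  out
}

#' Marginal log-likelihood of an event sequence
#'
#' Per visit, the likelihood marginalises the unknown stage over 0..N under the
#' stage prior, with independent Normal(expected severity, sigma) terms per
#' biomarker; missing biomarkers are skipped. Returns the weighted sum over
#' visits.
#'
#' @param z Severity matrix (visits x biomarkers), `z = -w`.
#' @param sequence Integer event-index sequence.
#' @param events An [ebm_events()] object.
#' @param control An [ebm_control()] object.
#' @param weights Optional per-visit weights (EM responsibilities).
#' @return Total log-likelihood (scalar).
#' @export
sequence_log_likelihood <- function(z, sequence, events,
                                    control = ebm_control(profile = "test"),
                                    weights = NULL) {
  z <- prepare_severities(z, events)
  stopifnot(is_valid_sequence(sequence, events))
  w <- weights %||% rep(1, nrow(z))
  stopifnot(length(w) == nrow(z))
  ebm_total_loglik_cpp(z, as.integer(sequence) - 1L, event_bio0(events),
                       events$table$threshold, length(events$biomarkers),
                       control$sigma, control$z_max,
                       log_stage_prior(events, control), w)
}

# per-visit marginal log-likelihood vector under one sequence
subject_log_likelihoods <- function(z, sequence, events, control) {
  LL <- ebm_loglik_matrix_cpp(z, as.integer(sequence) - 1L, event_bio0(events),
                              events$table$threshold,
                              length(events$biomarkers),
                              control$sigma, control$z_max)
  lp <- log_stage_prior(events, control)
  apply(sweep(LL, 2, lp, "+"), 1, logsumexp)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

greedy_fit <- function(z, events, control, weights, init = NULL) {
  init <- init %||% random_sequence(events)
  res <- ebm_greedy_cpp(z, as.integer(init) - 1L, event_bio0(events),
                        events$table$threshold, length(events$biomarkers),
                        control$sigma, control$z_max,
                        log_stage_prior(events, control), weights)
  list(sequence = as.integer(res$sequence) + 1L, loglik = res$loglik)
}

#' Fit a single maximum-likelihood event sequence
#'
#' Greedy ascent (steepest single-event repositioning) from `n_starts` random
#' valid sequences; the best start seeds a Metropolis chain whose proposals
#' move a random event to a random valid position. The ML sequence is the best
#' state visited by either phase.
#'
#' @inheritParams sequence_log_likelihood
#' @param seed Integer seed (all randomness in the fit flows from it).
#' @return List with `ml_sequence`, `ml_loglik`, `samples` (matrix of
#'   post-burn-in sequences by row, event indices), `sample_loglik`,
#'   `acceptance_rate`, `n_starts_loglik`.
#' @export
fit_single_sequence <- function(z, events,
                                control = ebm_control(profile = "test"),
                                seed = 1L, weights = NULL) {
  if (control$n_mcmc > 0 && control$n_mcmc < control$burn_in)
    stop("n_mcmc must be 0 or >= burn_in")
  z <- prepare_severities(z, events)
  if (length(events$biomarkers) < 2) stop("need at least 2 biomarkers")
  w <- weights %||% rep(1, nrow(z))
  set.seed(seed)
  starts <- lapply(seq_len(control$n_starts), function(i)
    greedy_fit(z, events, control, w))
  lls <- vapply(starts, `[[`, numeric(1), "loglik")
  best <- starts[[which.max(lls)]]
  samples <- NULL
  sample_ll <- NULL
  acc <- NA_real_
  if (control$n_mcmc > 0) {
    total_iter <- control$burn_in + control$n_mcmc
    mc <- ebm_mcmc_cpp(z, as.integer(best$sequence) - 1L, event_bio0(events),
                       events$table$threshold, length(events$biomarkers),
                       control$sigma, control$z_max,
                       log_stage_prior(events, control), w, total_iter)
    keep <- seq.int(control$burn_in + 1L, total_iter)
    samples <- mc$samples[keep, , drop = FALSE] + 1L
    sample_ll <- mc$loglik[keep]
    acc <- mc$acceptance_rate
    if (mc$ml_loglik > best$loglik) {
      best <- list(sequence = as.integer(mc$ml_sequence) + 1L,
                   loglik = mc$ml_loglik)
    }
  }
  list(ml_sequence = best$sequence, ml_loglik = best$loglik,
       samples = samples, sample_loglik = sample_ll,
       acceptance_rate = acc, n_starts_loglik = lls)
}

#' Fit a progression model with k subtypes
#'
#' For `k = 1` this is [fit_single_sequence()]. For `k > 1` the model is a
#' mixture of event sequences fitted by expectation-maximisation: the largest
#' cluster of the (k-1)-subtype solution is split by the best of several random
#' bipartitions, then responsibilities, responsibility-weighted greedy sequence
#' refits, and mixture fractions alternate until the relative log-likelihood
#' change falls below `em_tol`.
#'
#' @inheritParams fit_single_sequence
#' @param k Number of subtypes (>= 1).
#' @return An object of class `progression_model`: events, `k`, `sequences`
#'   (list of ML sequences), `fractions`, `mcmc` (per subtype: samples and
#'   log-likelihoods), `control`, `loglik` (total mixture log-likelihood).
#' @export
fit_subtypes <- function(z, events, k = 1L,
                         control = ebm_control(profile = "test"),
                         seed = 1L) {
  stopifnot(k >= 1)
  z <- prepare_severities(z, events)
  if (k == 1) {
    fit <- fit_single_sequence(z, events, control, seed = seed)
    model <- list(events = events, k = 1L, sequences = list(fit$ml_sequence),
                  fractions = 1, mcmc = list(list(samples = fit$samples,
                                                  loglik = fit$sample_loglik)),
                  control = control, loglik = fit$ml_loglik,
                  converged = TRUE)
    class(model) <- "progression_model"
    return(model)
  }
  parent <- fit_subtypes(z, events, k - 1L, control, seed = seed)
  set.seed(seed + k)
  state <- split_and_em(z, events, control, parent, retry = TRUE)
  # MCMC per subtype on responsibility-weighted data for positional uncertainty
  mcmc <- vector("list", k)
  if (control$n_mcmc > 0) {
    total_iter <- control$burn_in + control$n_mcmc
    for (c in seq_len(k)) {
      mc <- ebm_mcmc_cpp(z, as.integer(state$sequences[[c]]) - 1L,
                         event_bio0(events), events$table$threshold,
                         length(events$biomarkers), control$sigma,
                         control$z_max, log_stage_prior(events, control),
                         state$resp[, c], total_iter)
      keep <- seq.int(control$burn_in + 1L, total_iter)
      mcmc[[c]] <- list(samples = mc$samples[keep, , drop = FALSE] + 1L,
                        loglik = mc$loglik[keep])
    }
  }
  model <- list(events = events, k = as.integer(k),
                sequences = state$sequences, fractions = state$fractions,
                mcmc = mcmc, control = control, loglik = state$loglik,
                converged = state$converged)
  class(model) <- "progression_model"
  model
}

mixture_loglik <- function(ll_mat, fractions) {
  lw <- sweep(ll_mat, 2, log(fractions), "+")
  sum(apply(lw, 1, logsumexp))
}

split_and_em <- function(z, events, control, parent, retry = TRUE) {
  k <- parent$k + 1L
  n <- nrow(z)
  # responsibilities under the parent model
  ll_par <- vapply(parent$sequences, function(s)
    subject_log_likelihoods(z, s, events, control), numeric(n))
  ll_par <- matrix(ll_par, nrow = n)
  lw <- sweep(ll_par, 2, log(parent$fractions), "+")
  resp_par <- exp(lw - apply(lw, 1, logsumexp))
  big <- which.max(parent$fractions)

  best <- NULL
  for (r in seq_len(control$n_bipartitions)) {
    half <- runif(n) < 0.5
    w1 <- resp_par[, big] * half
    w2 <- resp_par[, big] * !half
    if (sum(w1) < 1 || sum(w2) < 1) next
    s1 <- greedy_fit(z, events, control, w1, init = parent$sequences[[big]])
    s2 <- greedy_fit(z, events, control, w2, init = parent$sequences[[big]])
    seqs <- c(parent$sequences[-big], list(s1$sequence, s2$sequence))
    fr <- c(parent$fractions[-big], rep(parent$fractions[big] / 2, 2))
    ll_mat <- vapply(seqs, function(s)
      subject_log_likelihoods(z, s, events, control), numeric(n))
    ll <- mixture_loglik(matrix(ll_mat, nrow = n), fr)
    if (is.null(best) || ll > best$loglik)
      best <- list(sequences = seqs, fractions = fr, loglik = ll)
  }
  if (is.null(best)) stop("could not initialize subtype split")
  em_iterate(z, events, control, best, retry = retry)
}

em_iterate <- function(z, events, control, state, retry = TRUE) {
  n <- nrow(z)
  k <- length(state$sequences)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(control$max_em_iter)) {
    ll_mat <- vapply(state$sequences, function(s)
      subject_log_likelihoods(z, s, events, control), numeric(n))
    ll_mat <- matrix(ll_mat, nrow = n)
    lw <- sweep(ll_mat, 2, log(state$fractions), "+")
    resp <- exp(lw - apply(lw, 1, logsumexp))
    if (any(colSums(resp) < 1)) {
      if (retry) {
        # re-seed the empty cluster once from a random subject subset
        empty <- which(colSums(resp) < 1)
        for (c in empty) {
          w <- as.numeric(runif(n) < 0.3)
          state$sequences[[c]] <- greedy_fit(z, events, control, w)$sequence
        }
        return(em_iterate(z, events, control, state, retry = FALSE))
      }
      stop("empty cluster during subtype EM")
    }
    state$fractions <- colMeans(resp)
    for (c in seq_len(k)) {
      state$sequences[[c]] <- greedy_fit(z, events, control, resp[, c],
                                         init = state$sequences[[c]])$sequence
    }
    ll_mat <- vapply(state$sequences, function(s)
      subject_log_likelihoods(z, s, events, control), numeric(n))
    ll_mat <- matrix(ll_mat, nrow = n)
    cur <- mixture_loglik(ll_mat, state$fractions)
    if (is.finite(prev) && abs(cur - prev) < control$em_tol * abs(prev)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  # final polish: multi-start refit of each cluster under the converged
  # responsibilities, so clusters do not end in different local optima
  lw <- sweep(ll_mat, 2, log(state$fractions), "+")
  resp <- exp(lw - apply(lw, 1, logsumexp))
  for (c in seq_len(k)) {
    best <- greedy_fit(z, events, control, resp[, c],
                       init = state$sequences[[c]])
    for (r in seq_len(max(control$n_starts - 1, 0))) {
      cand <- greedy_fit(z, events, control, resp[, c])
      if (cand$loglik > best$loglik) best <- cand
    }
    state$sequences[[c]] <- best$sequence
  }
  ll_mat <- vapply(state$sequences, function(s)
    subject_log_likelihoods(z, s, events, control), numeric(n))
  ll_mat <- matrix(ll_mat, nrow = n)
  prev <- mixture_loglik(ll_mat, state$fractions)
  lw <- sweep(ll_mat, 2, log(state$fractions), "+")
  state$resp <- exp(lw - apply(lw, 1, logsumexp))
  state$loglik <- prev
  state$converged <- converged
  state
}

#' @export
print.progression_model <- function(x, ...) {
  cat(sprintf("Progression model: %d subtype(s), %d events, loglik %.2f\n",
              x$k, x$events$n_events, x$loglik))
  for (c in seq_len(x$k)) {
    cat(sprintf("  subtype %d (fraction %.2f): %s ...\n", c, x$fractions[c],
                paste(head(sequence_labels(x$sequences[[c]], x$events), 4),
                      collapse = " > ")))
  }
  invisible(x)
}

#' Select the number of subtypes by cross-validated information criterion
#'
#' Subjects are split into folds; for each candidate k a model is trained on
#' the complement of each fold and the fold's out-of-sample -2 log-likelihood
#' is accumulated (CVIC). The selected k minimises CVIC, ties going to the
#' smaller k.
#'
#' When the fitting control includes MCMC samples, each subtype's
#' out-of-sample likelihood is averaged over (thinned) posterior sequence
#' samples rather than evaluated at the ML sequence alone. Without this,
#' mixtures of near-identical sequences gain a spurious model-averaging
#' advantage over k = 1 on homogeneous data; sample-averaging gives every k
#' the same treatment of sequence uncertainty.
#'
#' @inheritParams fit_single_sequence
#' @param k_grid Candidate subtype counts (default 1:5).
#' @param folds Number of cross-validation folds (default 10).
#' @param repeats Independent repetitions of the fold split (default 1);
#'   CVIC is then the per-repeat mean of the summed out-of-fold deviance, and
#'   its SE is estimated from all repeats x folds fold contributions.
#' @param max_samples Cap on posterior sequence samples used per subtype when
#'   averaging (default 100; thinned evenly).
#' @param one_se_rule Apply the one-standard-error rule (default): the
#'   selected k is the smallest whose CVIC lies within one SE (of the fold-wise
#'   CVIC difference) of the minimum. CVIC differences between a homogeneous
#'   model and a redundant mixture are typically well inside fold noise, so
#'   plain argmin selection is a coin flip there; `FALSE` gives strict argmin
#'   with ties to the smaller k.
#' @return List with `k_star`, `table` (k, cvic, cvic_se_vs_min), and
#'   `fold_cvic` (repeats x folds rows, one column per k).
#' @export
select_model <- function(z, events, k_grid = 1:5, folds = 10, repeats = 1,
                         control = ebm_control(profile = "test"), seed = 1L,
                         max_samples = 100, one_se_rule = TRUE) {
  z <- prepare_severities(z, events)
  n <- nrow(z)
  if (n < folds) stop("need at least as many subjects as folds")
  set.seed(seed)
  fold_cvic <- matrix(NA_real_, repeats * folds, length(k_grid),
                      dimnames = list(NULL, k_grid))
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    if (min(table(fold_id)) < 2) stop("a fold has fewer than 2 subjects")
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      for (f in seq_len(folds)) {
        train <- z[fold_id != f, , drop = FALSE]
        test <- z[fold_id == f, , drop = FALSE]
        m <- fit_subtypes(train, events, k = k, control = control,
                          seed = seed + 1000L * f + 100000L * r)
        ll_mat <- vapply(seq_len(k), function(c)
          subtype_oos_loglik(test, m, c, events, control, max_samples),
          numeric(nrow(test)))
        ll_mat <- matrix(ll_mat, nrow = nrow(test))
        fold_cvic[(r - 1L) * folds + f, ki] <-
          (-2) * mixture_loglik(ll_mat, m$fractions)
      }
    }
  }
  cvic <- colSums(fold_cvic) / repeats
  kmin <- which.min(cvic)
  # SE of the per-repeat summed fold-wise difference to the minimiser
  se_vs_min <- vapply(seq_along(k_grid), function(ki)
    sd(fold_cvic[, ki] - fold_cvic[, kmin]) * sqrt(folds / repeats),
    numeric(1))
  if (one_se_rule) {
    ok <- cvic <= cvic[kmin] + se_vs_min
    k_star <- k_grid[which(ok)[1]]
  } else {
    k_star <- k_grid[kmin]
  }
  list(k_star = as.integer(k_star),
       table = data.frame(k = k_grid, cvic = as.numeric(cvic),
                          cvic_se_vs_min = se_vs_min),
       fold_cvic = fold_cvic)
}

# per-subject out-of-sample log-likelihood for one subtype, averaged over
# thinned MCMC sequence samples when available
subtype_oos_loglik <- function(test, model, c, events, control, max_samples) {
  samples <- model$mcmc[[c]]$samples
  if (is.null(samples) || nrow(samples) == 0) {
    return(subject_log_likelihoods(test, model$sequences[[c]], events,
                                   control))
  }
  idx <- unique(round(seq(1, nrow(samples),
                          length.out = min(max_samples, nrow(samples)))))
  ll <- vapply(idx, function(i)
    subject_log_likelihoods(test, as.integer(samples[i, ]), events, control),
    numeric(nrow(test)))
  ll <- matrix(ll, nrow = nrow(test))
  apply(ll, 1, logsumexp) - log(length(idx))
}

#' Assign atrophy stages to visits
#'
#' For each visit and subtype, the stage posterior over 0..N is proportional to
#' the stage prior times the severity likelihood under that subtype's ML
#' sequence. Subtype responsibilities are proportional to the mixture fraction
#' times the stage-marginalised likelihood; the reported MAP stage comes from
#' the argmax-responsibility subtype, posterior ties resolved to the lowest
#' stage (least atrophy).
#'
#' @param model A fitted [fit_subtypes()] model.
#' @param z Severity matrix (visits x biomarkers) with the training biomarkers.
#' @return A data.frame of class `stage_assignment` with `map_stage`,
#'   `map_probability`, `subtype`, subtype responsibilities, and the stage
#'   posterior of the assigned subtype as a matrix attribute `posterior`.
#' @export
assign_stages <- function(model, z) {
  events <- model$events
  z <- prepare_severities(z, events)
  control <- model$control
  n <- nrow(z)
  N <- events$n_events
  lp <- log_stage_prior(events, control)
  post <- array(NA_real_, c(n, N + 1, model$k))
  marg <- matrix(NA_real_, n, model$k)
  for (c in seq_len(model$k)) {
    LL <- ebm_loglik_matrix_cpp(z, as.integer(model$sequences[[c]]) - 1L,
                                event_bio0(events), events$table$threshold,
                                length(events$biomarkers), control$sigma,
                                control$z_max)
    lpost <- sweep(LL, 2, lp, "+")
    m <- apply(lpost, 1, logsumexp)
    post[, , c] <- exp(lpost - m)
    marg[, c] <- m
  }
  lw <- sweep(marg, 2, log(model$fractions), "+")
  resp <- exp(lw - apply(lw, 1, logsumexp))
  subtype <- max.col(resp, ties.method = "first")
  map_stage <- integer(n)
  map_prob <- numeric(n)
  posterior <- matrix(NA_real_, n, N + 1,
                      dimnames = list(NULL, 0:N))
  for (i in seq_len(n)) {
    p <- post[i, , subtype[i]]
    map_stage[i] <- which.max(p) - 1L  # ties -> lowest stage
    map_prob[i] <- p[map_stage[i] + 1L]
    posterior[i, ] <- p
  }
  out <- data.frame(map_stage = map_stage, map_probability = map_prob,
                    subtype = subtype)
  colnames(resp) <- paste0("resp_subtype", seq_len(model$k))
  out <- cbind(out, as.data.frame(resp))
  attr(out, "posterior") <- posterior
  class(out) <- c("stage_assignment", "data.frame")
  out
}
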