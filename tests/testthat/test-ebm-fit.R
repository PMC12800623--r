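test_that("noise-free severities give exact sequence recovery", {
  ev <- test_events()
  d <- direct_severities(200, seed = 5, noise_sd = 0)
  fit <- fit_single_sequence(d$z, ev,
                             ebm_control(profile = "test", n_mcmc = 0),
                             seed = 2)
  expect_identical(fit$ml_sequence, d$sequence)
  expect_equal(sequence_kendall(fit$ml_sequence, d$sequence, ev), 1)
})

test_that("greedy plus MCMC equals brute-force argmax on a tiny event space", {
  ev <- ebm_events(c("a", "b", "c"), thresholds = 1)
  set.seed(6)
  truth <- c(3L, 1L, 2L)
  G <- expected_trajectory(truth, ev)
  stages <- sample(0:3, 80, replace = TRUE)
  z <- G[stages + 1, ] + matrix(rnorm(80 * 3, 0, 0.6), 80)
  ctl <- ebm_control(profile = "test", n_starts = 4, n_mcmc = 500,
                     burn_in = 100)
  fit <- fit_single_sequence(z, ev, ctl, seed = 9)
  seqs <- all_valid_sequences(ev)
  lls <- apply(seqs, 1, function(s)
    sequence_log_likelihood(z, as.integer(s), ev, ctl))
  expect_equal(fit$ml_sequence, unname(as.integer(seqs[which.max(lls), ])))
  expect_equal(fit$ml_loglik, max(lls), tolerance = 1e-8)
})

test_that("fits are deterministic given the seed", {
  ev <- test_events()
  d <- direct_severities(60, seed = 10)
  ctl <- ebm_control(profile = "test", n_starts = 2, n_mcmc = 300,
                     burn_in = 50)
  f1 <- fit_single_sequence(d$z, ev, ctl, seed = 4)
  f2 <- fit_single_sequence(d$z, ev, ctl, seed = 4)
  expect_identical(f1$ml_sequence, f2$ml_sequence)
  expect_identical(f1$samples, f2$samples)
})

test_that("every MCMC sample respects the threshold-ordering constraint", {
  ev <- test_events()
  d <- direct_severities(50, seed = 12)
  fit <- fit_single_sequence(d$z, ev,
                             ebm_control(profile = "test", n_starts = 1,
                                         n_mcmc = 400, burn_in = 50),
                             seed = 3)
  idx <- seq(1, nrow(fit$samples), by = 7)
  ok <- apply(fit$samples[idx, ], 1, is_valid_sequence, events = ev)
  expect_true(all(ok))
})

test_that("a flat likelihood accepts almost every proposal", {
  ev <- test_events()
  d <- direct_severities(30, seed = 13)
  fit <- fit_single_sequence(d$z, ev,
                             ebm_control(profile = "test", sigma = 1e6,
                                         n_starts = 1, n_mcmc = 2000,
                                         burn_in = 100),
                             seed = 5)
  expect_gt(fit$acceptance_rate, 0.6)  # self-moves keep it below 1
  dens <- positional_density(fit$samples, ev)
  expect_true(all(abs(rowSums(dens) - 1) < 1e-8))
  # no event should stay pinned to one position under a flat likelihood
  expect_lt(max(dens), 0.9)
})

test_that("k = 1 subtype fit reduces to the single-sequence fit", {
  ev <- test_events()
  d <- direct_severities(80, seed = 14)
  m <- fit_subtypes(d$z, ev, k = 1,
                    control = ebm_control(profile = "test", n_starts = 2,
                                          n_mcmc = 200, burn_in = 50),
                    seed = 6)
  expect_equal(m$fractions, 1)
  expect_equal(m$k, 1L)
  expect_false(is.null(m$mcmc[[1]]$samples))
})

test_that("two well-separated subtypes are recovered with k = 2", {
  ev <- test_events()
  s1 <- default_true_sequence(ev)
  s2 <- reversed_sequence(s1, ev)
  d1 <- direct_severities(150, seed = 15, sequence = s1)
  d2 <- direct_severities(150, seed = 16, sequence = s2)
  z <- rbind(d1$z, d2$z)
  ctl <- ebm_control(profile = "test", n_starts = 2, n_mcmc = 200,
                     burn_in = 50, max_em_iter = 8)
  m <- fit_subtypes(z, ev, k = 2, control = ctl, seed = 7)
  taus <- sapply(m$sequences, function(s)
    c(sequence_kendall(s, s1, ev), sequence_kendall(s, s2, ev)))
  # one fitted sequence matches each generating sequence
  expect_gt(max(taus[1, ]), 0.9)
  expect_gt(max(taus[2, ]), 0.9)
  expect_true(which.max(taus[1, ]) != which.max(taus[2, ]))
  expect_true(all(abs(m$fractions - 0.5) < 0.1))
})

test_that("fitting k = 2 to homogeneous data degenerates as expected", {
  ev <- test_events()
  d <- direct_severities(400, seed = 17, noise_sd = 0.7)
  ctl <- ebm_control(profile = "test", n_starts = 2, n_mcmc = 0,
                     max_em_iter = 10)
  m <- fit_subtypes(d$z, ev, k = 2, control = ctl, seed = 8)
  tau_between <- sequence_kendall(m$sequences[[1]], m$sequences[[2]], ev)
  expect_true(min(m$fractions) < 0.15 || tau_between > 0.9)
})

test_that("stage assignment handles the degenerate extremes", {
  ev <- test_events()
  s <- default_true_sequence(ev)
  m <- list(events = ev, k = 1L, sequences = list(s), fractions = 1,
            mcmc = list(NULL), control = ebm_control(profile = "test"),
            loglik = 0, converged = TRUE)
  class(m) <- "progression_model"
  G <- expected_trajectory(s, ev)
  z <- rbind(rep(0, 8), G[25, ])
  colnames(z) <- ev$biomarkers
  st <- assign_stages(m, z)
  expect_equal(st$map_stage, c(0L, 24L))
  post <- attr(st, "posterior")
  expect_true(all(abs(rowSums(post) - 1) < 1e-8))
  expect_equal(st$map_probability, apply(post, 1, max))
  expect_equal(unname(which.max(post[1, ])) - 1L, 0L)
})

test_that("staging error stays within two stages on the default cohort", {
  co <- shared_cohort()
  stages <- shared_baseline_stages()
  truth <- co$truth$stages
  truth <- truth[truth$visit_index == 1, ]
  mae <- mean(abs(stages$stage -
                    truth$true_stage[match(stages$subject_id,
                                           truth$subject_id)]))
  expect_lte(mae, 2.0)
})

test_that("model selection is reproducible and consistent", {
  ev <- test_events()
  d <- direct_severities(120, seed = 18)
  ctl <- ebm_control(profile = "test", n_starts = 2, n_mcmc = 0,
                     max_em_iter = 5)
  s1 <- select_model(d$z, ev, k_grid = 1:2, folds = 4, control = ctl,
                     seed = 11)
  s2 <- select_model(d$z, ev, k_grid = 1:2, folds = 4, control = ctl,
                     seed = 11)
  expect_identical(s1$table, s2$table)
  expect_error(select_model(d$z[1:3, ], ev, k_grid = 1, folds = 4,
                            control = ctl, seed = 1), "folds")
})
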